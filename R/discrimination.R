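#' @include AllClasses.R
NULL

#' Flatten candidate patches into feature vectors
#'
#' Each candidate's log-spectrogram excerpt is flattened into a fixed-length
#' vector (length bins x frames). Standardisation happens at train/classify
#' time using the model's statistics, so identical patches always give
#' identical features.
#'
#' @param x a \linkS4class{CandidateSet}, a bins x frames matrix, or a
#'   bins x frames x n array.
#' @return numeric matrix, one row per candidate.
#' @export
extractFeatures <- function(x) {
  if (is(x, "CandidateSet")) x <- x@patches
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  t(matrix(x, d[1] * d[2], d[3]))
}

#' Train the second-pass whoop/non-whoop classifier
#'
#' Standardise features per dimension, project onto the smallest number of
#' principal components reaching \code{varianceTarget} cumulative explained
#' variance (capped at \code{maxComponents}), then fit a two-class Fisher
#' discriminant in PCA-score space with a ridge-regularised pooled
#' within-class covariance. The decision threshold is the midpoint of the
#' projected class means; scores above it are called whoop.
#'
#' @param features numeric matrix, samples x dimensions.
#' @param labels character or logical; TRUE/"whoop" marks the whoop class,
#'   anything else is pooled into non_whoop.
#' @param varianceTarget cumulative explained-variance target (default 0.95).
#' @param maxComponents cap on retained components (default 20).
#' @param ridge ridge fraction of mean within-class variance added to the
#'   pooled covariance diagonal (default 1e-6).
#' @param patchDim optional c(bins, frames) recorded on the model.
#' @return a \linkS4class{ClassifierModel}.
#' @export
trainClassifier <- function(features, labels, varianceTarget = 0.95,
                            maxComponents = 20L, ridge = 1e-6,
                            patchDim = NULL) {
  y <- if (is.logical(labels)) labels else labels == "whoop"
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 samples per class")
  mu <- colMeans(features)
  sc <- apply(features, 2L, stats::sd)
  sc[sc == 0] <- 1 # constant dimensions carry no information
  z <- sweep(sweep(features, 2L, mu), 2L, sc, `/`)
  p <- stats::prcomp(z, center = FALSE)
  cum <- cumsum(p$sdev^2) / sum(p$sdev^2)
  k <- min(which(cum >= varianceTarget)[1], maxComponents,
           nrow(features) - 1L, ncol(features), na.rm = TRUE)
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  s <- z %*% rot
  m1 <- colMeans(s[y, , drop = FALSE])
  m0 <- colMeans(s[!y, , drop = FALSE])
  c1 <- stats::cov(s[y, , drop = FALSE])
  c0 <- stats::cov(s[!y, , drop = FALSE])
  n1 <- sum(y); n0 <- sum(!y)
  sw <- ((n1 - 1) * c1 + (n0 - 1) * c0) / (n1 + n0 - 2)
  lam <- ridge * sum(diag(sw)) / k
  w <- tryCatch(solve(sw + diag(lam, k), m1 - m0),
                error = function(e)
                  stop("pooled within-class covariance is singular even ",
                       "after regularisation; increase `ridge`"))
  thr <- sum(w * (m1 + m0)) / 2
  model <- new("ClassifierModel", featureMean = mu, featureScale = sc,
               rotation = rot, explainedVar = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
               dfWeights = as.numeric(w), dfThreshold = thr,
               classLabels = c(positive = "whoop", negative = "non_whoop"),
               patchDim = as.integer(patchDim %||% c(0L, 0L)),
               trainError = 0)
  pred <- classify(model, features)
  model@trainError <- mean((pred$label == "whoop") != y)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify candidate features
#'
#' Projects standardised features through the model's PCA basis onto its
#' discriminant axis. A score exactly at the threshold is assigned
#' non_whoop (conservative tie-break).
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param features numeric matrix (samples x dims) or a
#'   \linkS4class{CandidateSet}.
#' @return data.frame with \code{score} and \code{label}.
#' @export
classify <- function(model, features) {
  if (is(features, "CandidateSet")) features <- extractFeatures(features)
  if (is.vector(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != length(model@featureMean))
    stop("feature dimensionality ", ncol(features),
         " does not match model (", length(model@featureMean), ")")
  z <- sweep(sweep(features, 2L, model@featureMean), 2L,
             model@featureScale, `/`)
  score <- as.numeric(z %*% model@rotation %*% model@dfWeights)
  label <- ifelse(score > model@dfThreshold,
                  model@classLabels[["positive"]],
                  model@classLabels[["negative"]])
  data.frame(score = score, label = label, stringsAsFactors = FALSE)
}

#' Held-out class overlap
#'
#' Fraction of labelled evaluation samples whose predicted class differs
#' from the truth. On whoop-vs-droplet material this is the quantity
#' reported as "overlap" between the two clouds in discriminant space.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param features evaluation features (disjoint from training).
#' @param labels true labels ("whoop" / anything else).
#' @return misclassification fraction in [0, 1].
#' @export
classOverlap <- function(model, features, labels) {
  if (NROW(features) == 0L) stop("empty evaluation set")
  y <- if (is.logical(labels)) labels else labels == "whoop"
  pred <- classify(model, features)
  mean((pred$label == "whoop") != y)
}
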