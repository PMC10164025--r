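#' Inverse-weight set: ICA scalp maps pooled across subjects
#'
#' Bundles a channels-by-components matrix of ICA inverse weights
#' ("activation patterns") with per-component metadata. Each column is the
#' spatial projection pattern (scalp map) of one independent component;
#' components from several subjects are simply concatenated column-wise and
#' the subject identity is metadata only.
#'
#' @param weights Numeric matrix, rows = channels, columns = components.
#'   At least 3 channels and 2 components; no missing values; no
#'   zero-variance column (a constant scalp map carries no correlation
#'   information and is rejected).
#' @param meta Optional data frame with one row per component. Recognized
#'   columns: `component_id` (unique, contiguous integers starting at 1),
#'   `subject`, `ic_index`, `iclabel_class` (one of brain, muscle, eye,
#'   heart, line_noise, channel_noise, other, or `NA`). Missing columns are
#'   filled with defaults.
#' @return An object of class `inverse_weight_set`: a list with elements
#'   `weights` and `meta`.
#' @examples
#' w <- matrix(rnorm(31 * 10), 31, 10)
#' ws <- inverse_weight_set(w)
#' dim(ws$weights)
#' @export
inverse_weight_set <- function(weights, meta = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop_icclust("weights must be a numeric matrix",
                 class = "icclust_validation_error")
  }
  if (anyNA(weights)) {
    stop_icclust("weights contains missing values",
                 class = "icclust_validation_error")
  }
  if (nrow(weights) < 3) {
    stop_icclust("need at least 3 channels (rows), got ", nrow(weights),
                 class = "icclust_validation_error")
  }
  if (ncol(weights) < 2) {
    stop_icclust("need at least 2 components (columns), got ", ncol(weights),
                 class = "icclust_validation_error")
  }
  sds <- apply(weights, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop_icclust("zero-variance component column(s): ",
                 paste(bad, collapse = ", "),
                 class = "icclust_zero_variance_error")
  }
  n <- ncol(weights)
  if (is.null(meta)) {
    meta <- data.frame(component_id = seq_len(n),
                       subject = NA_character_,
                       ic_index = seq_len(n),
                       iclabel_class = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != n) {
      stop_icclust("meta has ", nrow(meta), " rows but weights has ", n,
                   " components", class = "icclust_validation_error")
    }
    if (is.null(meta$component_id)) meta$component_id <- seq_len(n)
    if (anyDuplicated(meta$component_id) ||
        !identical(sort(as.integer(meta$component_id)), seq_len(n))) {
      stop_icclust("component_id must be the unique contiguous integers 1..",
                   n, class = "icclust_validation_error")
    }
    if (is.null(meta$subject)) meta$subject <- NA_character_
    if (is.null(meta$ic_index)) meta$ic_index <- seq_len(n)
    if (is.null(meta$iclabel_class)) meta$iclabel_class <- NA_character_
    allowed <- c("brain", "muscle", "eye", "heart", "line_noise",
                 "channel_noise", "other")
    bad_cls <- setdiff(stats::na.omit(unique(meta$iclabel_class)), allowed)
    if (length(bad_cls)) {
      stop_icclust("unknown iclabel_class value(s): ",
                   paste(bad_cls, collapse = ", "),
                   class = "icclust_validation_error")
    }
    meta <- meta[order(meta$component_id),
                 c("component_id", "subject", "ic_index", "iclabel_class")]
    rownames(meta) <- NULL
  }
  structure(list(weights = weights, meta = meta),
            class = "inverse_weight_set")
}

#' @export
print.inverse_weight_set <- function(x, ...) {
  cat("Inverse-weight set:", nrow(x$weights), "channels x",
      ncol(x$weights), "components\n")
  subs <- unique(stats::na.omit(x$meta$subject))
  if (length(subs)) cat("Subjects:", paste(subs, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise Pearson correlations between component scalp maps
#'
#' Computes the Pearson correlation (across channels, with the usual
#' centering) between every pair of inverse-weight columns. This is the
#' signed precursor of the similarity measure; because ICA determines each
#' component only up to polarity, the absolute value ([to_similarity()]) is
#' what clustering consumes.
#'
#' The result is symmetrized as `(R + t(R))/2` to remove floating-point
#' asymmetry and its diagonal is exactly 1.
#'
#' @param ws An [inverse_weight_set()].
#' @return An n-by-n numeric correlation matrix.
#' @seealso [to_similarity()]
#' @export
compute_correlation_matrix <- function(ws) {
  if (!inherits(ws, "inverse_weight_set")) ws <- inverse_weight_set(ws)
  r <- stats::cor(ws$weights)
  r <- symmetrize(r)
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  dimnames(r) <- NULL
  r
}

#' Absolute-correlation similarity matrix
#'
#' Elementwise absolute value of a correlation matrix. Scalp maps have no
#' absolute polarity, so `|r|` is the natural similarity between component
#' topographies: a map and its sign-flipped copy are maximally similar.
#'
#' @param cm Symmetric correlation matrix with unit diagonal (values in
#'   \eqn{[-1, 1]}).
#' @return Symmetric similarity matrix with values in \eqn{[0, 1]} and unit
#'   diagonal.
#' @export
to_similarity <- function(cm) {
  check_square_symmetric(cm, "correlation matrix")
  if (max(abs(cm)) > 1 + 1e-9) {
    stop_icclust("correlation matrix has entries outside [-1, 1]",
                 class = "icclust_validation_error")
  }
  if (max(abs(diag(cm) - 1)) > 1e-9) {
    stop_icclust("correlation matrix diagonal must be 1",
                 class = "icclust_validation_error")
  }
  j <- abs(symmetrize(cm))
  diag(j) <- 1
  j
}
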