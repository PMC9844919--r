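#' Labeled design matrix
#'
#' The universal dataset object of the package: an `n x p` numeric covariate
#' matrix with named columns plus a binary 0/1 response vector.
#'
#' @param X numeric matrix of covariates; columns are named (`X1..Xp` assigned
#'   when missing).
#' @param y integer/numeric vector of 0/1 responses, `length(y) == nrow(X)`.
#' @return an object of class `labeled_design` with elements `X` and `y`.
#' @export
labeled_design <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop_invalid("nrow(X) must equal length(y)")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop_invalid("response must be binary 0/1")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  structure(list(X = X, y = y), class = "labeled_design")
}

#' @export
print.labeled_design <- function(x, ...) {
  cat(sprintf("labeled_design: %d rows, %d covariates, %d cases (%.4f case fraction)\n",
              nrow(x$X), ncol(x$X), sum(x$y), mean(x$y)))
  invisible(x)
}

#' @export
dim.labeled_design <- function(x) dim(x$X)

#' Read / write labeled datasets as delimited text
#'
#' Schema: a header row of covariate names followed by a final `y` column;
#' comma-separated by default, tab-separated when `sep = "\t"`.
#'
#' @param path file path.
#' @param sep field separator, `","` or `"\t"`.
#' @return `read_labeled_csv` returns a [labeled_design()].
#' @export
read_labeled_csv <- function(path, sep = ",") {
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  if (!"y" %in% names(dt)) stop_invalid("dataset file must contain a 'y' column")
  y <- dt[["y"]]
  X <- as.matrix(dt[, setdiff(names(dt), "y"), drop = FALSE])
  labeled_design(X, y)
}

#' @param data a [labeled_design()].
#' @rdname read_labeled_csv
#' @export
write_labeled_csv <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "labeled_design"))
  df <- data.frame(data$X, check.names = FALSE)
  df$y <- data$y
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Serialize / load a truth manifest
#'
#' The truth manifest records which covariates carry signal in a synthetic
#' dataset: the signal index set, the nonzero coefficients keyed by covariate
#' name, and the intercept used at generation time.
#'
#' @param truth a `truth_manifest` (see [simulate_dataset()]).
#' @param path JSON file path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_manifest"))
  jsonlite::write_json(
    list(signal_indices = truth$signal_indices,
         coefficients = as.list(truth$coefficient_map[truth$signal_indices]),
         alpha = truth$alpha,
         p = truth$p),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.integer(j$p)
  cm <- numeric(p)
  names(cm) <- paste0("X", seq_len(p))
  cm[names(j$coefficients)] <- unlist(j$coefficients)
  truth_manifest(signal_indices = as.integer(j$signal_indices),
                 coefficient_map = cm, alpha = j$alpha, p = p)
}

#' Construct a truth manifest
#'
#' @param signal_indices integer indices of the signal covariates.
#' @param coefficient_map full length-`p` named coefficient vector (zeros for
#'   noise covariates).
#' @param alpha intercept used in the generating model.
#' @param p covariate count.
#' @return an object of class `truth_manifest` with `signal_indices`,
#'   `noise_indices`, `coefficient_map`, `alpha`, `p`.
#' @export
truth_manifest <- function(signal_indices, coefficient_map, alpha, p) {
  signal_indices <- sort(as.integer(signal_indices))
  if (length(coefficient_map) != p) stop_invalid("coefficient_map must have length p")
  if (any(signal_indices < 1L | signal_indices > p)) stop_invalid("signal indices out of range")
  structure(list(signal_indices = signal_indices,
                 noise_indices = setdiff(seq_len(p), signal_indices),
                 coefficient_map = coefficient_map,
                 alpha = alpha, p = as.integer(p)),
            class = "truth_manifest")
}
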