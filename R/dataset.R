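#' Create a labeled dataset
#'
#' A labeled dataset is a list of frames, each holding an
#' [atomic_configuration()] plus (optionally) its reference potential energy
#' (eV) and per-atom forces (eV/Angstrom). Frames may carry a `split` tag
#' (`"train"` / `"validation"`) assigned by [split_dataset()].
#'
#' @param frames List of lists with fields `config`, and optionally `energy`,
#'   `forces`, `split` and `extra` (extra per-atom columns carried through
#'   file round trips).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(frames) {
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!inherits(fr$config, "atomic_configuration")) {
      stop("frame ", k, ": config must be an atomic_configuration")
    }
    if (!is.null(fr$energy) && !is.finite(fr$energy)) {
      stop("frame ", k, ": energy must be finite")
    }
    if (!is.null(fr$forces)) {
      fr$forces <- as.matrix(fr$forces)
      if (!all(dim(fr$forces) == c(n_atoms(fr$config), 3L))) {
        stop("frame ", k, ": forces shape does not match the atom count")
      }
      frames[[k]]$forces <- fr$forces
    }
  }
  structure(frames, class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  na <- vapply(x, function(fr) n_atoms(fr$config), integer(1))
  cat("<labeled_dataset> ", length(x), " frames, ",
      min(na), "-", max(na), " atoms, ",
      sum(vapply(x, function(fr) !is.null(fr$forces), logical(1))),
      " with forces\n", sep = "")
  invisible(x)
}

#' @export
`[.labeled_dataset` <- function(x, i) {
  structure(unclass(x)[i], class = "labeled_dataset")
}

#' Randomly split a dataset into training and validation parts
#'
#' Tags each frame with `"train"` or `"validation"`. The validation set size
#' is `floor(n * (1 - fraction))` and the training set takes the remainder
#' (so 741 frames at fraction 0.9 give 667 training and 74 validation
#' frames); the assignment is a seeded random permutation.
#'
#' @param ds A [labeled_dataset()] with at least 2 frames.
#' @param fraction Training fraction, strictly between 0 and 1 (default 0.9).
#' @param seed Integer seed.
#' @return The dataset with `split` tags set.
#' @export
split_dataset <- function(ds, fraction = 0.9, seed = 1L) {
  n <- length(ds)
  if (n < 2L) stop("need at least 2 frames to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_val <- floor(n * (1 - fraction))
  n_val <- max(1L, min(n - 1L, n_val))
  perm <- with_seed(seed, sample.int(n))
  tags <- rep("train", n)
  tags[perm[seq_len(n_val)]] <- "validation"
  for (k in seq_len(n)) ds[[k]]$split <- tags[k]
  ds
}

#' Extract one split of a tagged dataset
#'
#' @param ds A dataset tagged by [split_dataset()].
#' @param which `"train"` or `"validation"`.
#' @return The `labeled_dataset` subset.
#' @export
dataset_subset <- function(ds, which = c("train", "validation")) {
  which <- match.arg(which)
  tags <- vapply(ds, function(fr) fr$split %||% NA_character_, character(1))
  if (anyNA(tags)) stop("dataset has untagged frames; run split_dataset() first")
  ds[tags == which]
}
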