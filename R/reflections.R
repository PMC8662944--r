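#' Reflection set
#'
#' Observed structure-factor amplitudes with uncertainties and
#' cross-validation (free-set) flags.
#'
#' @param hkl integer n x 3 matrix of Miller indices (unique rows)
#' @param fobs observed amplitudes (electrons, > 0)
#' @param sigma amplitude uncertainties (> 0)
#' @param free logical free-set flags; the free fraction must be <= 0.5.
#'   Free reflections never enter refinement targets, scales or
#'   sigma-A estimates.
#' @return object of class `reflection_set`
#' @export
reflection_set <- function(hkl, fobs, sigma, free = rep(FALSE, length(fobs))) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  n <- nrow(hkl)
  if (length(fobs) != n || length(sigma) != n || length(free) != n)
    stop("hkl, fobs, sigma and free must have matching lengths")
  if (anyDuplicated(hkl)) stop("duplicate Miller indices")
  if (any(fobs <= 0)) stop("amplitudes must be positive")
  if (any(sigma <= 0)) stop("sigmas must be strictly positive")
  free <- as.logical(free)
  if (mean(free) > 0.5) stop("free-set fraction must be in [0, 0.5]")
  structure(list(hkl = hkl, fobs = as.numeric(fobs),
                 sigma = as.numeric(sigma), free = free),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set: %d reflections (%d free)\n",
              length(x$fobs), sum(x$free)))
  invisible(x)
}

#' Resolution of reflections
#'
#' @param cell a [unit_cell()]
#' @param hkl n x 3 integer matrix
#' @return d-spacings in Angstrom
#' @export
d_spacing <- function(cell, hkl) {
  g <- hkl %*% cell$cart2frac      # reciprocal-lattice vectors, 1/A
  1 / sqrt(rowSums(g^2))
}

#' Read/write reflections as TSV
#'
#' Whitespace-separated columns `h k l fobs sigma free` with `free` in
#' \{0, 1\}; a header line is optional.
#'
#' @param path file path
#' @return a [reflection_set()]
#' @export
read_reflections <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("[A-Za-z]", first)
  tb <- utils::read.table(path, header = header, comment.char = "#")
  if (ncol(tb) < 6) stop("reflection TSV needs 6 columns: h k l fobs sigma free")
  names(tb)[1:6] <- c("h", "k", "l", "fobs", "sigma", "free")
  reflection_set(cbind(tb$h, tb$k, tb$l), tb$fobs, tb$sigma, tb$free != 0)
}

#' @rdname read_reflections
#' @param refl a [reflection_set()]
#' @export
write_reflections <- function(refl, path) {
  tb <- data.frame(h = refl$hkl[, 1], k = refl$hkl[, 2], l = refl$hkl[, 3],
                   fobs = refl$fobs, sigma = refl$sigma,
                   free = as.integer(refl$free))
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read amplitudes from a structure-factor mmCIF loop
#'
#' Minimal reader for `_refln`-style loops carrying
#' `index_h/index_k/index_l`, `F_meas_au`, `F_meas_sigma_au` (or
#' `F_meas_sigma`) and optionally `status` (`f` marks free reflections) or
#' `pdbx_r_free_flag`.
#'
#' @param path mmCIF file
#' @return a [reflection_set()]
#' @export
read_reflections_cif <- function(path) {
  ln <- readLines(path, warn = FALSE)
  i <- which(trimws(ln) == "loop_")
  for (start in i) {
    j <- start + 1
    tags <- character(0)
    while (j <= length(ln) && grepl("^\\s*_refln", ln[j])) {
      tags <- c(tags, trimws(ln[j])); j <- j + 1
    }
    if (!length(tags)) next
    if (!any(grepl("index_h", tags))) next
    rows <- list()
    while (j <= length(ln)) {
      s <- trimws(ln[j])
      if (s == "" || grepl("^(loop_|_|#|data_)", s)) break
      rows[[length(rows) + 1]] <- strsplit(s, "\\s+")[[1]]
      j <- j + 1
    }
    m <- do.call(rbind, rows)
    tag_of <- function(p) {
      k <- grep(p, tags)
      if (length(k)) k[1] else NA_integer_
    }
    ih <- tag_of("index_h$"); ik <- tag_of("index_k$"); il <- tag_of("index_l$")
    iF <- tag_of("F_meas(_au)?$"); iS <- tag_of("F_meas_sigma(_au)?$")
    ist <- tag_of("\\.status$"); ifr <- tag_of("r_free_flag$")
    if (any(is.na(c(ih, ik, il, iF)))) next
    fobs <- as.numeric(m[, iF])
    sig <- if (!is.na(iS)) as.numeric(m[, iS]) else pmax(0.01 * fobs, 1e-6)
    free <- if (!is.na(ist)) m[, ist] == "f"
            else if (!is.na(ifr)) m[, ifr] == "0"
            else rep(FALSE, nrow(m))
    keep <- is.finite(fobs) & fobs > 0
    return(reflection_set(
      cbind(as.integer(m[keep, ih]), as.integer(m[keep, ik]),
            as.integer(m[keep, il])),
      fobs[keep], pmax(sig[keep], 1e-6), free[keep]))
  }
  stop("no _refln loop with amplitudes found in ", path)
}
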