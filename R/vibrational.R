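#' Spectroscopic band lists
#'
#' A band is a single wavenumber (`lo == hi`) or an interval (`lo < hi`,
#' e.g. the C-O-C envelope 1030-1160 cm^-1), with a free-text assignment
#' label and a presence flag: tabulated comparisons sometimes print "-" for a
#' mode a method fails to produce, which is modelled as `present = FALSE` and
#' never enters any matching.
#'
#' @param lo,hi Band bounds in cm^-1, `0 < lo <= hi`; for single-valued bands
#'   pass `hi = lo` (the default).
#' @param assignment Character assignment labels (recycled).
#' @param present Logical presence flags (recycled).
#' @param source Free-text provenance tag (`"experimental"`, a model tag, ...).
#' @return Object of class `band_list`: a `data.frame` with columns `lo`,
#'   `hi`, `assignment`, `present`, sorted by `lo`, plus a `source` attribute.
#' @export
band_list <- function(lo, hi = lo, assignment = "", present = TRUE,
                      source = "") {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == length(hi))
  if (any(!(lo > 0) | hi < lo))
    stop("bands must satisfy 0 < lo <= hi")
  df <- data.frame(lo = lo, hi = hi,
                   assignment = rep_len(as.character(assignment), length(lo)),
                   present = rep_len(as.logical(present), length(lo)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$lo, df$hi), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("band_list", "data.frame"), source = source)
}

#' @export
print.band_list <- function(x, ...) {
  cat(sprintf("<band_list> %s: %d band(s)\n", attr(x, "source"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read / write a band list as CSV
#'
#' CSV columns: `lo`, `hi`, `assignment`, `present`.
#'
#' @param path CSV path.
#' @param source Source tag attached on read (defaults to the file name).
#' @param bl A [band_list()] to write.
#' @return `read_band_list` returns a [band_list()]; `write_band_list`
#'   returns `path` invisibly.
#' @export
read_band_list <- function(path, source = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in c("lo", "hi")) if (is.null(df[[f]])) stop("band CSV missing column '", f, "'")
  band_list(df$lo, df$hi,
            assignment = if (is.null(df$assignment)) "" else df$assignment,
            present = if (is.null(df$present)) TRUE else df$present,
            source = source)
}

#' @rdname read_band_list
#' @export
write_band_list <- function(bl, path) {
  stopifnot(inherits(bl, "band_list"))
  utils::write.csv(as.data.frame(bl), path, row.names = FALSE)
  invisible(path)
}

#' Scale harmonic frequencies
#'
#' Multiplies computed harmonic wavenumbers by a scaling factor (the standard
#' correction for the systematic overestimation of harmonic force fields).
#' Imaginary modes, encoded as negative wavenumbers, are excluded with a
#' warning: scaling them is meaningless.
#'
#' @param freqs Wavenumbers in cm^-1.
#' @param factor Positive scaling factor.
#' @return Scaled wavenumbers (imaginary modes removed).
#' @export
apply_scale <- function(freqs, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("scaling factor must be a single positive number")
  freqs <- as.numeric(freqs)
  if (any(freqs < 0)) {
    warning(sprintf("excluding %d imaginary mode(s) from scaling", sum(freqs < 0)))
    freqs <- freqs[freqs >= 0]
  }
  freqs * factor
}

#' Effective scaling factor from paired calculated/experimental frequencies
#'
#' Least-squares slope through the origin of experimental versus calculated
#' wavenumbers: `sum(calc*exp) / sum(calc^2)`. Scale-equivariant: scaling
#' `calc` by c scales the estimate by 1/c.
#'
#' @param calc,exp Equal-length paired wavenumber vectors, length >= 2.
#' @return The dimensionless factor.
#' @export
estimate_scale <- function(calc, exp) {
  calc <- as.numeric(calc); exp <- as.numeric(exp)
  if (length(calc) != length(exp)) stop("'calc' and 'exp' must have equal length")
  if (length(calc) < 2L) stop("at least two pairs are required")
  sum(calc * exp) / sum(calc^2)
}

# distance between two bands: 0 if the intervals overlap, otherwise the gap
# between nearest endpoints (reduces to |a - b| for two single-valued bands)
band_distance <- function(lo1, hi1, lo2, hi2) {
  pmax(0, pmax(lo2 - hi1, lo1 - hi2))
}

# Monotone one-to-one matching of two sorted band lists by dynamic
# programming: each skipped band costs `tol`, each pair costs its residual,
# so a pair forms only when cheaper than skipping both sides.  With
# tol = Inf skipping is maximally penalized, yielding the row-aligned
# matching of equal-length tables.
match_monotone <- function(a, b, tol) {
  n <- nrow(a); m <- nrow(b)
  skip <- if (is.finite(tol)) tol else 1e9
  cost <- matrix(0, n + 1L, m + 1L)
  cost[, 1L] <- (0:n) * skip
  cost[1L, ] <- (0:m) * skip
  move <- matrix(0L, n + 1L, m + 1L)  # 1 = pair, 2 = skip model band, 3 = skip exp band
  move[, 1L] <- 2L; move[1L, ] <- 3L; move[1L, 1L] <- 0L
  for (i in seq_len(n)) {
    r_i <- band_distance(a$lo[i], a$hi[i], b$lo, b$hi)
    for (j in seq_len(m)) {
      pair <- cost[i, j] + r_i[j]
      skip_a <- cost[i, j + 1L] + skip
      skip_b <- cost[i + 1L, j] + skip
      # prefer pairing on ties so maximal matchings survive tol = Inf
      if (pair <= skip_a && pair <= skip_b) {
        cost[i + 1L, j + 1L] <- pair; move[i + 1L, j + 1L] <- 1L
      } else if (skip_a <= skip_b) {
        cost[i + 1L, j + 1L] <- skip_a; move[i + 1L, j + 1L] <- 2L
      } else {
        cost[i + 1L, j + 1L] <- skip_b; move[i + 1L, j + 1L] <- 3L
      }
    }
  }
  pairs <- matrix(integer(0), ncol = 2L)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    mv <- move[i + 1L, j + 1L]
    if (mv == 1L) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) i <- i - 1L else j <- j - 1L
  }
  pairs
}

#' Assign model bands to experimental bands
#'
#' One-to-one monotone (order-preserving) matching of the two sorted lists,
#' minimizing total residual by dynamic programming. Band order is physically
#' meaningful in vibrational spectra, so crossing assignments are never
#' produced. The residual to an interval band is 0 inside (or overlapping)
#' the interval, else the distance to the nearest endpoint. Pairs whose
#' residual exceeds `tol` are dissolved into the unmatched lists. Bands with
#' `present = FALSE` never participate.
#'
#' @param model,exp [band_list()] objects.
#' @param tol Positive matching tolerance in cm^-1 (default 100, suited to
#'   model-vs-experiment comparison); `Inf` forces maximal matching.
#' @return Object of class `band_assignment`: list with `pairs` (data.frame
#'   of matched model/exp bands with `residual` and `both_single`),
#'   `unmatched_model`, `unmatched_exp` (band data.frames), and the source
#'   tags.
#' @export
assign_bands <- function(model, exp, tol = 100) {
  stopifnot(inherits(model, "band_list"), inherits(exp, "band_list"), tol > 0)
  a <- as.data.frame(model)[model$present, , drop = FALSE]
  b <- as.data.frame(exp)[exp$present, , drop = FALSE]
  pm <- if (nrow(a) && nrow(b)) match_monotone(a, b, tol) else matrix(integer(0), ncol = 2L)
  if (nrow(pm)) {
    res <- band_distance(a$lo[pm[, 1L]], a$hi[pm[, 1L]],
                         b$lo[pm[, 2L]], b$hi[pm[, 2L]])
    keep <- res <= tol
    pm <- pm[keep, , drop = FALSE]
    res <- res[keep]
  } else res <- numeric(0)
  pairs <- data.frame(
    model_lo = a$lo[pm[, 1L]], model_hi = a$hi[pm[, 1L]],
    exp_lo = b$lo[pm[, 2L]], exp_hi = b$hi[pm[, 2L]],
    model_assignment = a$assignment[pm[, 1L]],
    exp_assignment = b$assignment[pm[, 2L]],
    residual = res,
    both_single = (a$lo[pm[, 1L]] == a$hi[pm[, 1L]]) &
                  (b$lo[pm[, 2L]] == b$hi[pm[, 2L]]),
    stringsAsFactors = FALSE)
  structure(list(
    pairs = pairs,
    unmatched_model = a[setdiff(seq_len(nrow(a)), pm[, 1L]), , drop = FALSE],
    unmatched_exp = b[setdiff(seq_len(nrow(b)), pm[, 2L]), , drop = FALSE],
    model_source = attr(model, "source"), exp_source = attr(exp, "source"),
    tol = tol), class = "band_assignment")
}

#' @export
print.band_assignment <- function(x, ...) {
  cat(sprintf("<band_assignment> %s vs %s (tol %g cm^-1): %d pair(s), %d/%d unmatched\n",
              x$model_source, x$exp_source, x$tol, nrow(x$pairs),
              nrow(x$unmatched_model), nrow(x$unmatched_exp)))
  if (nrow(x$pairs)) print.data.frame(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Error score of a band assignment
#'
#' Mean absolute deviation and root-mean-square deviation over matched pairs.
#' Interval pairs are excluded by default: the overlap residual of two
#' intervals is not a like-for-like distance, so only single-valued pairs
#' enter the error by default.
#'
#' @param ar A [assign_bands()] result.
#' @param model Model tag carried into the score (defaults to the
#'   assignment's model source).
#' @param include_intervals Include pairs involving interval bands?
#' @return Object of class `model_score`: list with `model`, `mad`, `rmsd`,
#'   `n_matched` (all pairs) and `n_scored` (pairs entering the error).
#' @export
model_error <- function(ar, model = ar$model_source, include_intervals = FALSE) {
  stopifnot(inherits(ar, "band_assignment"))
  if (!nrow(ar$pairs)) stop("no matched pairs: model error undefined")
  r <- if (include_intervals) ar$pairs$residual else ar$pairs$residual[ar$pairs$both_single]
  if (!length(r)) stop("no scored pairs: all matches involve interval bands")
  structure(list(model = model, mad = mean(abs(r)), rmsd = sqrt(mean(r^2)),
                 n_matched = nrow(ar$pairs), n_scored = length(r)),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("<model_score> %s: MAD %.2f cm^-1, RMSD %.2f cm^-1 (%d scored / %d matched)\n",
              x$model, x$mad, x$rmsd, x$n_scored, x$n_matched))
  invisible(x)
}

#' Rank method/basis models by band error
#'
#' @param scores List of `model_score` objects.
#' @return A `data.frame` ordered ascending by MAD, ties broken by RMSD then
#'   model tag; columns `model`, `mad`, `rmsd`, `n_matched`, `n_scored`.
#' @export
rank_models <- function(scores) {
  if (inherits(scores, "model_score")) scores <- list(scores)
  stopifnot(length(scores) >= 1,
            all(vapply(scores, inherits, logical(1), "model_score")))
  df <- data.frame(
    model = vapply(scores, `[[`, character(1), "model"),
    mad = vapply(scores, `[[`, numeric(1), "mad"),
    rmsd = vapply(scores, `[[`, numeric(1), "rmsd"),
    n_matched = vapply(scores, `[[`, numeric(1), "n_matched"),
    n_scored = vapply(scores, `[[`, numeric(1), "n_scored"),
    stringsAsFactors = FALSE)
  df <- df[order(df$mad, df$rmsd, df$model), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Differential band detection between two spectra
#'
#' Matches two experimental band lists monotonically (as in
#' [assign_bands()]) and classifies: bands of `b` unmatched within `tol` are
#' *new*, bands of `a` unmatched are *lost*, matched pairs report the signed
#' shift `b - a` (midpoint difference for interval bands). The default
#' tolerance of 50 cm^-1 suits experiment-vs-experiment comparison, where a
#' genuinely new chemical feature (e.g. a carbonyl band appearing on
#' functionalization) sits far from any shifted parent band.
#'
#' @param a,b [band_list()] objects (before / after).
#' @param tol Positive matching tolerance in cm^-1.
#' @return Object of class `band_diff`: list with `new` (bands of `b`),
#'   `lost` (bands of `a`), and `shifted` (data.frame of matched pairs with
#'   signed `shift` and `both_single`).
#' @export
diff_bands <- function(a, b, tol = 50) {
  ar <- assign_bands(a, b, tol = tol)
  p <- ar$pairs
  mid_a <- (p$model_lo + p$model_hi) / 2
  mid_b <- (p$exp_lo + p$exp_hi) / 2
  shifted <- data.frame(
    a_lo = p$model_lo, a_hi = p$model_hi, b_lo = p$exp_lo, b_hi = p$exp_hi,
    assignment = ifelse(nzchar(p$exp_assignment), p$exp_assignment, p$model_assignment),
    shift = mid_b - mid_a, both_single = p$both_single,
    stringsAsFactors = FALSE)
  structure(list(new = ar$unmatched_exp, lost = ar$unmatched_model,
                 shifted = shifted,
                 a_source = attr(a, "source"), b_source = attr(b, "source"),
                 tol = tol), class = "band_diff")
}

#' @export
print.band_diff <- function(x, ...) {
  cat(sprintf("<band_diff> %s -> %s (tol %g cm^-1)\n", x$a_source, x$b_source, x$tol))
  cat(sprintf("  new: %s\n", if (nrow(x$new)) paste(x$new$lo, collapse = ", ") else "none"))
  cat(sprintf("  lost: %s\n", if (nrow(x$lost)) paste(x$lost$lo, collapse = ", ") else "none"))
  if (nrow(x$shifted)) {
    cat("  shifts:\n")
    print.data.frame(x$shifted, row.names = FALSE)
  }
  invisible(x)
}
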