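#' Hartree to electronvolt conversion
#'
#' @param x Energy in hartree.
#' @param constant eV per hartree; the default 27.2114 reproduces tabulated
#'   3-decimal conversions in this literature. Pass the full CODATA value
#'   (27.211386245988) if preferred.
#' @return Energy in eV.
#' @export
hartree_to_ev <- function(x, constant = 27.2114) x * constant

#' Fragment decomposition of a complex
#'
#' @param complex_label Label of the assembled complex.
#' @param complex_TE Total energy of the complex (hartree).
#' @param fragments Named numeric vector (or named list) of fragment total
#'   energies in hartree; at least one fragment.
#' @param site_tag Free-text tag of the functionalization site
#'   (e.g. `"center"`, `"terminal"`).
#' @return Object of class `fragment_set`.
#' @export
fragment_set <- function(complex_label, complex_TE, fragments, site_tag = "") {
  fragments <- unlist(fragments)
  if (!length(fragments)) stop("at least one fragment is required")
  if (!all(is.finite(c(complex_TE, fragments))))
    stop("all total energies must be finite")
  structure(list(complex_label = complex_label,
                 complex_TE = as.numeric(complex_TE),
                 fragments = fragments, site_tag = site_tag),
            class = "fragment_set")
}

#' Fragment binding energy
#'
#' BE = TE(complex) - sum TE(fragments), in hartree and eV. Negative values
#' indicate favorable association. The raw difference is always reported;
#' no sign convention is imposed on top of the arithmetic.
#'
#' @param fs A [fragment_set()].
#' @param constant Conversion constant passed to [hartree_to_ev()].
#' @return Object of class `binding_result` with fields `BE_au`, `BE_eV`,
#'   `site_tag`, `complex_label`.
#' @examples
#' fs <- fragment_set("cellulose-OH-center", -1973.132,
#'                    c(cellulose = -1898.381, OH = -75.311), "center")
#' binding_energy(fs)
#' @export
binding_energy <- function(fs, constant = 27.2114) {
  stopifnot(inherits(fs, "fragment_set"))
  be <- fs$complex_TE - sum(fs$fragments)
  structure(list(complex_label = fs$complex_label,
                 BE_au = be, BE_eV = hartree_to_ev(be, constant),
                 site_tag = fs$site_tag),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("<binding_result> %s [%s]: BE = %.6f hartree = %.3f eV (%s)\n",
              x$complex_label, x$site_tag, x$BE_au, x$BE_eV,
              if (x$BE_au < 0) "favorable" else "unfavorable"))
  invisible(x)
}

#' Rank candidate functionalization sites by binding energy
#'
#' @param results List of `binding_result` objects (or a single one).
#' @return The list ordered ascending by `BE_au` (most negative, i.e. most
#'   favorable, first); ties broken by `site_tag` lexicographically.
#' @export
rank_sites <- function(results) {
  if (inherits(results, "binding_result")) results <- list(results)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "binding_result")))
  be <- vapply(results, `[[`, numeric(1), "BE_au")
  tag <- vapply(results, `[[`, character(1), "site_tag")
  results[order(be, tag)]
}
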