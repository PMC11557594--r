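#' Global reactivity descriptors from frontier orbital energies
#'
#' The Koopmans-type descriptor cascade of conceptual DFT: from a HOMO/LUMO
#' pair (eV) derive the ionization potential I = -E_HOMO, electron affinity
#' A = -E_LUMO, electronegativity chi = (I+A)/2, chemical potential mu = -chi,
#' global hardness eta = (I-A)/2, softness sigma = 1/eta, and electrophilicity
#' index omega = mu^2/(2 eta). All energies in eV, sigma in 1/eV.
#'
#' @name reactivity-descriptors
NULL

#' @describeIn reactivity-descriptors HOMO-LUMO gap, `lumo - homo` (eV).
#' @param homo,lumo Frontier orbital energies in eV.
#' @export
gap <- function(homo, lumo) {
  if (any(lumo < homo))
    stop("lumo < homo: record should have failed validation")
  lumo - homo
}

#' @describeIn reactivity-descriptors Ionization potential `-homo` (eV).
#' @export
ionization_potential <- function(homo) -homo

#' @describeIn reactivity-descriptors Electron affinity `-lumo` (eV).
#' @export
electron_affinity <- function(lumo) -lumo

#' @describeIn reactivity-descriptors Electronegativity `(I + A)/2` (eV).
#' @param I,A Ionization potential and electron affinity in eV.
#' @export
electronegativity <- function(I, A) (I + A) / 2

#' @describeIn reactivity-descriptors Chemical potential `-(I + A)/2` (eV).
#' @export
chemical_potential <- function(I, A) -electronegativity(I, A)

#' @describeIn reactivity-descriptors Global hardness `(I - A)/2` (eV); warns
#'   when I < A (unbound ordering).
#' @export
hardness <- function(I, A) {
  if (any(I < A)) warning("I < A: hardness negative, system not bound in the usual sense")
  (I - A) / 2
}

#' @describeIn reactivity-descriptors Softness `1/eta` (1/eV).
#' @param eta Global hardness in eV.
#' @param label Structure label used in the division-by-zero error message.
#' @export
softness <- function(eta, label = "structure") {
  if (any(eta == 0))
    stop(sprintf("softness undefined for '%s': hardness is zero", label))
  1 / eta
}

#' @describeIn reactivity-descriptors Electrophilicity index `mu^2/(2 eta)`
#'   (eV); requires `eta > 0`.
#' @param mu Chemical potential in eV.
#' @export
electrophilicity <- function(mu, eta) {
  if (any(eta <= 0)) stop("electrophilicity requires eta > 0")
  mu^2 / (2 * eta)
}

#' @describeIn reactivity-descriptors Euclidean dipole magnitude in Debye;
#'   accepts a 3-vector or an already-scalar magnitude.
#' @param v Dipole vector (Debye).
#' @export
dipole_magnitude <- function(v) {
  v <- as.numeric(v)
  if (length(v) == 1L) abs(v) else sqrt(sum(v^2))
}

#' Reference metal for the electron-transfer fraction
#'
#' Parameters of the metal surface entering the fraction of transferred
#' electrons Delta N. The default is the literal parameterization used with
#' iron in the corrosion-inhibition literature this package follows:
#' chi_ref = 0, eta_ref = 7 eV, with a *difference* in the denominator,
#' Delta N = (chi_ref - chi_inh) / (2 (eta_ref - eta_inh)). The conventional
#' textbook rule (chi_Fe = 7 eV, eta_Fe = 0, a *sum* in the denominator) is
#' selectable via `rule = "sum"` with the matching reference values.
#'
#' @param chi_ref Reference electronegativity (eV).
#' @param eta_ref Reference hardness (eV).
#' @param rule `"difference"` or `"sum"`: how reference and inhibitor hardness
#'   combine in the denominator.
#' @return An object of class `reference_metal`.
#' @export
reference_metal <- function(chi_ref = 0, eta_ref = 7, rule = c("difference", "sum")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(chi_ref), is.numeric(eta_ref))
  structure(list(chi_ref = chi_ref, eta_ref = eta_ref, rule = rule),
            class = "reference_metal")
}

#' Fraction of transferred electrons between inhibitor and metal
#'
#' @param chi_inh,eta_inh Inhibitor electronegativity and hardness (eV).
#' @param ref A [reference_metal()].
#' @return Dimensionless Delta N.
#' @examples
#' electron_transfer_fraction(2.530, 3.972, reference_metal())  # -0.4177...
#' @export
electron_transfer_fraction <- function(chi_inh, eta_inh, ref = reference_metal()) {
  stopifnot(inherits(ref, "reference_metal"))
  denom <- switch(ref$rule,
                  difference = 2 * (ref$eta_ref - eta_inh),
                  sum        = 2 * (ref$eta_ref + eta_inh))
  if (any(denom == 0)) stop("electron transfer fraction: zero denominator under rule '",
                            ref$rule, "'")
  (ref$chi_ref - chi_inh) / denom
}

#' Full descriptor set for one HOMO/LUMO pair
#'
#' @param homo,lumo Frontier orbital energies (eV).
#' @param ref A [reference_metal()] for Delta N, or `NULL` to skip it.
#' @param dipole Optional dipole (vector or magnitude, Debye).
#' @param label Structure label.
#' @return Object of class `descriptor_set`: a named list with `gap`, `I`,
#'   `A`, `chi`, `mu`, `eta`, `sigma`, `omega`, and optionally `dN` and `tdm`.
#' @export
reactivity_descriptors <- function(homo, lumo, ref = reference_metal(),
                                   dipole = NULL, label = "structure") {
  g <- gap(homo, lumo)
  I <- ionization_potential(homo)
  A <- electron_affinity(lumo)
  chi <- electronegativity(I, A)
  mu <- chemical_potential(I, A)
  eta <- hardness(I, A)
  sg <- softness(eta, label)
  om <- electrophilicity(mu, eta)
  dN <- if (!is.null(ref)) electron_transfer_fraction(chi, eta, ref) else NA_real_
  tdm <- if (!is.null(dipole)) dipole_magnitude(dipole) else NA_real_
  structure(list(label = label, gap = g, I = I, A = A, chi = chi, mu = mu,
                 eta = eta, sigma = sg, omega = om, dN = dN, tdm = tdm),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, digits = 3, ...) {
  cat(sprintf("<descriptor_set> %s\n", x$label))
  v <- unlist(x[c("gap", "I", "A", "chi", "mu", "eta", "sigma", "omega", "dN", "tdm")])
  print(round(v, digits))
  invisible(x)
}

#' Round half away from zero
#'
#' The rounding convention of printed descriptor tables in this literature
#' (base `round()` rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Descriptor table for a record set
#'
#' One row per structure with the full cascade at working precision plus
#' columns rounded half-away-from-zero at `digits` decimals (the printing
#' convention of the reference tables). A structure whose record fails
#' (e.g. no virtual orbital) yields a row of `NA`s with the error message in
#' the `error` column; one bad structure never aborts the table.
#'
#' @param rs A [record_set()].
#' @param ref A [reference_metal()] or `NULL`.
#' @param digits Decimals for the rounded view (default 3).
#' @return A `data.frame` with columns `label`, `homo`, `lumo`, `gap`, `I`,
#'   `A`, `chi`, `mu`, `eta`, `sigma`, `omega`, `dN`, `tdm`, their
#'   `.r`-suffixed rounded counterparts, and `error`.
#' @export
descriptor_table <- function(rs, ref = reference_metal(), digits = 3) {
  stopifnot(inherits(rs, "record_set"))
  cols <- c("gap", "I", "A", "chi", "mu", "eta", "sigma", "omega", "dN", "tdm")
  rows <- lapply(rs$records, function(r) {
    out <- tryCatch({
      hl <- homo_lumo(r)
      d <- reactivity_descriptors(hl["homo"], hl["lumo"], ref = ref,
                                  dipole = r$dipole, label = r$label)
      c(list(label = r$label, homo = unname(hl["homo"]), lumo = unname(hl["lumo"])),
        lapply(d[cols], unname), list(error = NA_character_))
    }, error = function(e) {
      c(list(label = r$label, homo = NA_real_, lumo = NA_real_),
        stats::setNames(as.list(rep(NA_real_, length(cols))), cols),
        list(error = conditionMessage(e)))
    })
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  if (is.null(tab)) {
    tab <- as.data.frame(stats::setNames(
      c(list(character(0), numeric(0), numeric(0)),
        rep(list(numeric(0)), length(cols)), list(character(0))),
      c("label", "homo", "lumo", cols, "error")))
  }
  for (cc in cols) tab[[paste0(cc, ".r")]] <- round_half_away(tab[[cc]], digits)
  tab
}

#' Compare a computed descriptor table with a printed reference table
#'
#' Printed tables carry finite precision and occasionally internal
#' inconsistencies; this check compares each computed full-precision value
#' against the printed cell with tolerance `tol` on the printed scale and
#' *flags* failures instead of silently tolerating them.
#'
#' @param computed Numeric vector of full-precision values.
#' @param printed Numeric vector of printed reference values (same length,
#'   `NA` for cells with no reference).
#' @param tol Absolute tolerance on the printed scale (default 0.0015, i.e.
#'   agreement to 3 printed decimals plus rounding slack).
#' @param labels Optional cell labels for the report.
#' @return A `data.frame` with `label`, `computed`, `printed`, `delta`,
#'   `consistent` (logical; `NA` where no reference). Class
#'   `consistency_report`; its print method lists the flagged cells.
#' @export
compare_to_reference <- function(computed, printed, tol = 0.0015, labels = NULL) {
  stopifnot(length(computed) == length(printed))
  if (is.null(labels)) labels <- paste0("cell", seq_along(computed))
  delta <- computed - printed
  out <- data.frame(label = labels, computed = computed, printed = printed,
                    delta = delta, consistent = abs(delta) <= tol,
                    stringsAsFactors = FALSE)
  class(out) <- c("consistency_report", "data.frame")
  attr(out, "tol") <- tol
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  tol <- attr(x, "tol")
  bad <- x[!is.na(x$consistent) & !x$consistent, , drop = FALSE]
  cat(sprintf("consistency report: %d cell(s), tol %.4g; %d flagged\n",
              nrow(x), tol, nrow(bad)))
  if (nrow(bad)) print.data.frame(bad, row.names = FALSE, digits = 6)
  invisible(x)
}
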