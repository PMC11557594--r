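# run code under an explicit seed without disturbing global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# symmetric Dirichlet draws via normalized gammas
rdirichlet_sym <- function(n, k, concentration) {
  g <- matrix(stats::rgamma(n * k, shape = concentration, rate = 1), nrow = n)
  g / rowSums(g)
}

#' Parameters of the synthetic structure-summary generator
#'
#' Controls seeded generation of [qc_record()] fixtures with the statistical
#' structure the analysis stages assume: an occupied and a virtual orbital
#' cluster separated by a prescribed gap, Dirichlet population-weight rows,
#' a normal dipole vector, and harmonic frequency sets with a known true
#' scaling factor plus additive noise.
#'
#' Defaults emulate the cellulose-model summaries the reference tables
#' describe: a ~7.9 eV insulator-like gap, three atom groups (C, H, O),
#' and a frequency set over the mid-IR with a scaling factor of 0.9614 and
#' 5 cm^-1 experimental noise.
#'
#' @param seed Integer seed; every draw from this spec is deterministic.
#' @param n_occupied,n_virtual Orbital counts per cluster (>= 1).
#' @param gap Minimum HOMO-LUMO gap in eV (>= 0).
#' @param occupied_spread,virtual_spread Cluster standard deviations, eV (> 0).
#' @param n_groups Number of named atom groups for population weights.
#' @param dirichlet_concentration Symmetric Dirichlet concentration (> 0).
#' @param n_freqs Number of harmonic frequencies.
#' @param true_scale True frequency scaling factor.
#' @param freq_noise_sd Additive Gaussian noise on "experimental"
#'   frequencies, cm^-1 (>= 0).
#' @param dipole_scale Standard deviation of dipole components, Debye.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_occupied = 20L, n_virtual = 20L,
                           gap = 7.944, occupied_spread = 2, virtual_spread = 2,
                           n_groups = 3L, dirichlet_concentration = 1,
                           n_freqs = 30L, true_scale = 0.9614,
                           freq_noise_sd = 5, dipole_scale = 2) {
  stopifnot(n_occupied >= 1, n_virtual >= 1, gap >= 0,
            occupied_spread > 0, virtual_spread > 0,
            n_groups >= 1, dirichlet_concentration > 0,
            n_freqs >= 1, true_scale > 0, freq_noise_sd >= 0, dipole_scale > 0)
  structure(list(seed = as.integer(seed), n_occupied = as.integer(n_occupied),
                 n_virtual = as.integer(n_virtual), gap = gap,
                 occupied_spread = occupied_spread, virtual_spread = virtual_spread,
                 n_groups = as.integer(n_groups),
                 dirichlet_concentration = dirichlet_concentration,
                 n_freqs = as.integer(n_freqs), true_scale = true_scale,
                 freq_noise_sd = freq_noise_sd, dipole_scale = dipole_scale),
            class = "synthetic_spec")
}

#' Generate a synthetic structure-summary record
#'
#' Occupied energies are drawn as a normal cluster centred one spread below
#' `-gap/2` and clipped to at most `-gap/2`; virtual energies mirror this
#' above `+gap/2`, and the frontier pair is pinned at exactly `-gap/2` /
#' `+gap/2`, so the generated record satisfies `lumo - homo == gap` exactly.
#' Population weight rows are symmetric Dirichlet
#' draws over `n_groups` named groups; dipole components are centred normal;
#' frequencies are sorted uniform draws over the mid-IR window
#' 400-3800 cm^-1.
#'
#' @param spec A [synthetic_spec()].
#' @param label Record label.
#' @return A valid [qc_record()]; identical for identical specs.
#' @export
gen_qc_record <- function(spec, label = sprintf("synthetic-%d", spec$seed)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$gap <= 0)
    stop("record generation requires a positive gap (occupied must lie below virtual)")
  with_seed(spec$seed, {
    occ <- stats::rnorm(spec$n_occupied,
                        mean = -spec$gap / 2 - spec$occupied_spread,
                        sd = spec$occupied_spread)
    occ <- pmin(occ, -spec$gap / 2)
    occ[which.max(occ)] <- -spec$gap / 2
    vir <- stats::rnorm(spec$n_virtual,
                        mean = spec$gap / 2 + spec$virtual_spread,
                        sd = spec$virtual_spread)
    vir <- pmax(vir, spec$gap / 2)
    vir[which.min(vir)] <- spec$gap / 2
    n_orb <- spec$n_occupied + spec$n_virtual
    w <- rdirichlet_sym(n_orb, spec$n_groups, spec$dirichlet_concentration)
    colnames(w) <- if (spec$n_groups <= 3) c("C", "H", "O")[seq_len(spec$n_groups)]
                   else paste0("group", seq_len(spec$n_groups))
    dip <- stats::rnorm(3, 0, spec$dipole_scale)
    freqs <- sort(stats::runif(spec$n_freqs, 400, 3800))
    # orbital sort in the constructor must not detach weights from energies:
    # pass them pre-sorted
    e <- c(occ, vir)
    occ_flag <- rep(c(TRUE, FALSE), c(spec$n_occupied, spec$n_virtual))
    ord <- order(e)
    qc_record(label, e[ord], occ_flag[ord],
              method = "synthetic", basis = "synthetic",
              dipole = dip, frequencies = freqs,
              population_weights = w[ord, , drop = FALSE])
  })
}

#' Generate a paired calculated/experimental frequency set
#'
#' `calc` is drawn uniformly over 400-3800 cm^-1 and sorted;
#' `exp = true_scale * calc + N(0, freq_noise_sd)`, returned sorted ascending.
#' With `freq_noise_sd = 0`, [estimate_scale()] recovers `true_scale`
#' exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return List with sorted numeric vectors `calc` and `exp`.
#' @export
gen_freq_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    calc <- sort(stats::runif(spec$n_freqs, 400, 3800))
    exp <- spec$true_scale * calc + stats::rnorm(spec$n_freqs, 0, spec$freq_noise_sd)
    list(calc = calc, exp = sort(exp))
  })
}

#' Generate a record set from a list of specs
#'
#' @param specs List of [synthetic_spec()] objects.
#' @param labels Unique labels, one per spec (default `synthetic-<seed>`;
#'   seeds must then be unique).
#' @return A [record_set()] suitable for [descriptor_table()] and DOS/PDOS
#'   batch runs.
#' @export
gen_record_set <- function(specs, labels = NULL) {
  stopifnot(all(vapply(specs, inherits, logical(1), "synthetic_spec")))
  if (is.null(labels))
    labels <- vapply(specs, function(s) sprintf("synthetic-%d", s$seed), character(1))
  if (anyDuplicated(labels))
    stop("duplicate record label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  record_set(mapply(gen_qc_record, specs, labels, SIMPLIFY = FALSE),
             provenance = "synthetic generator")
}
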