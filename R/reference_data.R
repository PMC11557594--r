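#' Reference tables: cellulose functionalization study
#'
#' Published reference values for a three-unit cellulose model functionalized
#' with OH, NH2, COOH, CH3, CHO, CN, SH and graphene oxide (GO) at the
#' CH2OH terminal site, computed at the DFT B3LYP/3-21G** level, plus the
#' corresponding experimental and computed FTIR band tables. These are the
#' worked-example inputs for every stage of the package and the fixtures of
#' its validation suite.
#'
#' All functions return plain data frames built in code (no external files):
#'
#' * `ref_frontier_orbitals()` — LUMO/HOMO energies (eV) and the printed
#'   descriptor cascade (I, A, mu, eta, sigma, omega) for the nine
#'   structures.
#' * `ref_gap_tdm()` — printed total dipole moment (Debye) and HOMO-LUMO
#'   gap (eV) per structure.
#' * `ref_binding()` — total energies (hartree) of the OH fragment, the bare
#'   cellulose model and the two OH-functionalized complexes
#'   (center/terminal), with the printed binding energies in hartree and eV.
#' * `ref_ir_experimental()` — the experimental FTIR bands of cellulose film
#'   as a [band_list()] (intervals for the C-O-C and CH3-umbrella
#'   envelopes).
#' * `ref_ir_models()` — named list of [band_list()]s, one per method/basis
#'   column of the scaled computed IR tables (HF and B3LYP with 3-21G,
#'   6-31G, 6-311G, LANL2DZ, LANL2MB, plus B3LYP/3-21G**). The C-O mode,
#'   which no computed column reproduces, carries `present = FALSE`.
#' * `ref_ir_composite()` — the experimental FTIR bands of the cellulose-GO
#'   composite film, including the new carboxyl band at 1710 cm^-1.
#'
#' @name reference-tables
NULL

ref_structures <- c("Cellulose", "Cellulose-OH", "Cellulose-NH2",
                    "Cellulose-COOH", "Cellulose-CH3", "Cellulose-CHO",
                    "Cellulose-CN", "Cellulose-SH", "Cellulose-GO")

#' @rdname reference-tables
#' @return `ref_frontier_orbitals()`: data.frame with `label`, `lumo`,
#'   `homo`, `I`, `A`, `mu`, `eta`, `sigma`, `omega` (printed values).
#' @export
ref_frontier_orbitals <- function() {
  data.frame(
    label = ref_structures,
    lumo = c(1.442, 0.179, 1.597, 0.973, 1.638, 0.055, 0.819, -0.524, -4.076),
    homo = c(-6.502, -6.475, -6.419, -6.533, -6.435, -6.610, -6.642, -6.492, -4.244),
    I = c(6.502, 6.475, 6.419, 6.533, 6.435, 6.610, 6.642, 6.492, 4.244),
    A = c(-1.442, -0.179, -1.597, -0.973, -1.638, -0.055, -0.819, 0.524, 4.076),
    mu = c(-2.530, -3.148, -2.410, -2.779, -2.398, -3.277, -2.911, -3.508, -4.156),
    eta = c(3.972, 3.327, 4.008, 3.754, 4.037, 3.333, 3.731, 2.984, 0.084),
    sigma = c(0.252, 0.300, 0.249, 0.266, 0.248, 0.300, 0.268, 0.335, 11.855),
    omega = c(0.806, 1.489, 0.725, 1.029, 0.712, 1.611, 1.136, 2.063, 102.575),
    stringsAsFactors = FALSE)
}

#' @rdname reference-tables
#' @return `ref_gap_tdm()`: data.frame with `label`, `tdm` (Debye), `gap`
#'   (eV) as printed.
#' @export
ref_gap_tdm <- function() {
  data.frame(
    label = ref_structures,
    tdm = c(4.353, 4.051, 4.212, 2.123, 2.997, 3.391, 6.957, 3.188, 63.975),
    gap = c(7.944, 6.654, 8.017, 7.507, 8.074, 6.665, 6.571, 5.968, 0.168),
    stringsAsFactors = FALSE)
}

#' @rdname reference-tables
#' @return `ref_binding()`: list with `fragments` (named hartree energies of
#'   `OH` and `Cellulose`) and `complexes` (data.frame of the two complexes
#'   with total energy and printed binding energies).
#' @export
ref_binding <- function() {
  list(
    fragments = c(OH = -75.311, Cellulose = -1898.381),
    complexes = data.frame(
      label = c("Cellulose-OH-Center", "Cellulose-OH-Terminal"),
      site = c("center", "terminal"),
      TE = c(-1973.132, -1973.103),
      BE_au_printed = c(-0.564, -0.594),
      BE_eV_printed = c(-15.347, -16.163),
      stringsAsFactors = FALSE))
}

ir_assignments <- c("CH2", "C-H", "C-O-C", "C-CO", "C-CH",
                    "split CH3 umbrella", "C-H bend", "C-O", "CH sym. str.",
                    "O-H stretch")

#' @rdname reference-tables
#' @export
ref_ir_experimental <- function() {
  band_list(lo = c(615, 895, 1030, 1280, 1320, 1340, 1430, 1640, 2900, 3345),
            hi = c(615, 895, 1160, 1280, 1320, 1370, 1430, 1640, 2900, 3345),
            assignment = ir_assignments,
            source = "experimental")
}

#' @rdname reference-tables
#' @export
ref_ir_models <- function() {
  # columns in experimental band order: CH2, C-H, C-O-C(lo,hi), C-CO, C-CH,
  # CH3 umbrella(lo,hi), C-H bend, C-O (absent everywhere), CH sym, O-H
  cols <- list(
    "HF/3-21G"      = list(633, 872, c(1031, 1167), 1276, 1324, c(1345, 1377), 1430, NA, 2990, 3342),
    "HF/6-31G"      = list(633, 874, c(1042, 1175), 1279, 1328, c(1346, 1381), 1436, NA, 2941, 3512),
    "HF/6-311G"     = list(630, 877, c(1046, 1178), 1282, 1334, c(1350, 1383), 1432, NA, 2945, 3563),
    "HF/LANL2DZ"    = list(631, 867, c(1035, 1168), 1269, 1318, c(1335, 1373), 1428, NA, 2960, 3537),
    "HF/LANL2MB"    = list(607, 931, c(1138, 1263), 1373, 1438, c(1456, 1494), 1586, NA, 3166, 3800),
    "B3LYP/3-21G"   = list(637, 890, c(1029, 1122), 1278, 1324, c(1343, 1374), 1418, NA, 2943, 3388),
    "B3LYP/6-31G"   = list(629, 716, c(1029, 1132), 1273, 1308, c(1339, 1370), 1417, NA, 2956, 3503),
    "B3LYP/6-311G"  = list(629, 723, c(1028, 1131), 1274, 1312, c(1339, 1371), 1393, NA, 2934, 3551),
    "B3LYP/LANL2DZ" = list(611, 850, c(1092, 1167), 1311, 1375, c(1396, 1422), 1562, NA, 3105, 3537),
    "B3LYP/LANL2MB" = list(611, 851, c(1092, 1167), 1311, 1375, c(1396, 1422), 1595, NA, 3105, 3537),
    "B3LYP/3-21G**" = list(635, 849, c(1022, 1117), 1281, 1320, c(1339, 1371), 1417, NA, 3021, 3619))
  lapply(stats::setNames(names(cols), names(cols)), function(tag) {
    v <- cols[[tag]]
    lo <- vapply(v, function(x) if (all(is.na(x))) 1 else min(x), numeric(1))
    hi <- vapply(v, function(x) if (all(is.na(x))) 1 else max(x), numeric(1))
    present <- !vapply(v, function(x) all(is.na(x)), logical(1))
    band_list(lo, hi, assignment = ir_assignments, present = present, source = tag)
  })
}

#' @rdname reference-tables
#' @export
ref_ir_composite <- function() {
  band_list(lo = c(605, 875, 1010, 1280, 1306, 1320, 1410, 1620, 1710, 2880, 3325),
            hi = c(605, 875, 1140, 1280, 1306, 1350, 1410, 1620, 1710, 2880, 3325),
            assignment = c(ir_assignments[1:8], "COOH of GO",
                           ir_assignments[9:10]),
            source = "cellulose-GO composite")
}
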