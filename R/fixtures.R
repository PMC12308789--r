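# Deterministic fixtures: a frozen library of small molecules with
# hand-verified titratable-site tables, and a synthetic training-table
# generator with a planted linear energy signal. Everything here is
# reproducible with no download.

.TOY_COORDS <- list(
  water = list(
    elements = c("O", "H", "H"),
    coords = matrix(c(
      0.0062, 0.3978, 0.0000,
      -0.7665, -0.1870, 0.0000,
      0.7603, -0.2107, 0.0000
    ), ncol = 3L, byrow = TRUE)
  ),
  ammonia = list(
    elements = c("N", "H", "H", "H"),
    coords = matrix(c(
      0.0006, -0.0008, 0.2956,
      0.8918, -0.2954, -0.1011,
      -0.7022, -0.6244, -0.0990,
      -0.1901, 0.9206, -0.0956
    ), ncol = 3L, byrow = TRUE)
  ),
  ethane = list(
    elements = c("C", "C", "H", "H", "H", "H", "H", "H"),
    coords = matrix(c(
      -0.7540, -0.0482, 0.0275,
      0.7540, 0.0482, -0.0275,
      -1.0883, -1.0366, -0.3015,
      -1.1126, 0.1147, 1.0483,
      -1.2112, 0.7040, -0.6223,
      1.1126, -0.1147, -1.0483,
      1.0883, 1.0366, 0.3015,
      1.2112, -0.7040, 0.6223
    ), ncol = 3L, byrow = TRUE)
  ),
  pyridine = list(
    elements = c("C", "C", "C", "N", "C", "C", "H", "H", "H", "H", "H"),
    coords = matrix(c(
      0.1355, 1.1751, 0.0479,
      1.2462, 0.3429, -0.0447,
      1.0371, -1.0260, -0.0979,
      -0.1847, -1.6014, -0.0652,
      -1.2440, -0.7679, 0.0248,
      -1.1360, 0.6124, 0.0836,
      0.2599, 2.2532, 0.0918,
      2.2504, 0.7501, -0.0746,
      1.8719, -1.7171, -0.1705,
      -2.2146, -1.2548, 0.0494,
      -2.0216, 1.2334, 0.1554
    ), ncol = 3L, byrow = TRUE)
  ),
  acetic_acid = list(
    elements = c("C", "C", "O", "O", "H", "H", "H", "H"),
    coords = matrix(c(
      -0.9509, -0.1526, -0.0263,
      0.4672, 0.3069, -0.1056,
      0.8662, 1.3495, -0.5946,
      1.3242, -0.5760, 0.4395,
      -1.6008, 0.5998, -0.4820,
      -1.0672, -1.0916, -0.5730,
      -1.2419, -0.2779, 1.0195,
      2.2031, -0.1581, 0.3224
    ), ncol = 3L, byrow = TRUE)
  ),
  glycine = list(
    elements = c("N", "C", "C", "O", "O", "H", "H", "H", "H", "H"),
    coords = matrix(c(
      -0.6000, 1.1896, 0.6304,
      -0.5348, -0.2762, 0.5017,
      0.7151, -0.7153, -0.2483,
      1.3275, -1.7582, -0.0818,
      1.0806, 0.1406, -1.2305,
      -1.5509, 1.4634, 0.8689,
      -0.3986, 1.5923, -0.2882,
      -0.5189, -0.7190, 1.5015,
      -1.4060, -0.6450, -0.0480,
      1.8861, -0.2722, -1.6057
    ), ncol = 3L, byrow = TRUE)
  ),
  ethanolamine = list(
    elements = c("N", "C", "C", "O", "H", "H", "H", "H", "H", "H", "H"),
    coords = matrix(c(
      1.6855, -0.2174, 0.1633,
      0.3361, -0.5226, -0.3029,
      -0.6908, 0.5488, 0.0799,
      -1.9847, 0.1987, -0.3964,
      1.9995, 0.6597, -0.2521,
      1.6807, -0.0668, 1.1714,
      0.3464, -0.6489, -1.3915,
      0.0248, -1.4902, 0.1070,
      -0.7463, 0.6725, 1.1667,
      -0.4218, 1.5150, -0.3591,
      -2.2294, -0.6488, 0.0136
    ), ncol = 3L, byrow = TRUE)
  ),
  imidazole = list(
    elements = c("C", "C", "N", "C", "N", "H", "H", "H", "H"),
    coords = matrix(c(
      1.0859, -0.5875, -0.0119,
      0.6896, 0.7265, 0.0674,
      -0.6767, 0.6873, 0.0293,
      -1.0471, -0.6237, -0.0697,
      -0.0017, -1.4178, -0.0967,
      2.0945, -0.9803, -0.0125,
      1.2416, 1.6520, 0.1448,
      -1.3042, 1.4787, 0.0670,
      -2.0820, -0.9351, -0.1177
    ), ncol = 3L, byrow = TRUE)
  ),
  formamide = list(
    elements = c("N", "C", "O", "H", "H", "H"),
    coords = matrix(c(
      -0.6901, 0.0609, -0.0015,
      0.6646, -0.0442, 0.0090,
      1.2659, -0.9977, -0.4595,
      -1.1786, 0.8538, 0.3886,
      -1.2229, -0.6907, -0.4194,
      1.1610, 0.8179, 0.4828
    ), ncol = 3L, byrow = TRUE)
  ),
  cysteine = list(
    elements = c("N", "C", "C", "S", "C", "O", "O", "H", "H", "H", "H",
                 "H", "H", "H"),
    coords = matrix(c(
      0.2421, 1.7168, 0.6708,
      0.5226, 0.4690, -0.0820,
      -0.6902, -0.0809, -0.8495,
      -2.1943, -0.2757, 0.1685,
      1.0958, -0.6013, 0.8513,
      1.0637, -0.6120, 2.0723,
      1.6843, -1.6162, 0.1825,
      -0.4723, 2.2544, 0.1815,
      -0.1940, 1.4460, 1.5590,
      1.3134, 0.7129, -0.8017,
      -0.4619, -1.0546, -1.2955,
      -0.9439, 0.6015, -1.6682,
      -2.9775, -0.7610, -0.8065,
      2.0122, -2.1988, 0.9009
    ), ncol = 3L, byrow = TRUE)
  ),
  thiolane_acid = list(
    elements = c("O", "C", "O", "C", "C", "C", "C", "S", "H", "H", "H",
                 "H", "H", "H", "H", "H"),
    coords = matrix(c(
      -2.6050, 0.7296, 0.8785,
      -1.8101, -0.1822, 0.2734,
      -2.2456, -0.8297, -0.6640,
      -0.4158, -0.2055, 0.8762,
      0.4619, 0.8847, 0.2723,
      1.0308, 0.3286, -1.0271,
      1.5959, -1.0441, -0.7082,
      0.4585, -1.7637, 0.5064,
      -3.4584, 0.6428, 0.4024,
      -0.5049, -0.1025, 1.9624,
      1.2813, 1.1318, 0.9597,
      -0.0950, 1.8095, 0.0857,
      1.8056, 0.9860, -1.4353,
      0.2429, 0.2501, -1.7867,
      2.5879, -0.9627, -0.2532,
      1.6700, -1.6727, -1.5997
    ), ncol = 3L, byrow = TRUE)
  ),
  bromoaniline = list(
    elements = c("N", "C", "C", "C", "C", "Br", "C", "C", "H", "H", "H",
                 "H", "H", "H"),
    coords = matrix(c(
      2.3278, -0.2306, 0.4090,
      0.9700, -0.0753, 0.1106,
      0.2170, -1.1675, -0.3301,
      -1.1639, -1.0552, -0.5171,
      -1.8036, 0.1453, -0.2209,
      -3.6708, 0.3019, -0.4672,
      -1.0772, 1.2246, 0.2749,
      0.3033, 1.1031, 0.4587,
      2.8505, 0.6397, 0.4173,
      2.7899, -0.9520, -0.1357,
      0.7009, -2.1193, -0.5328,
      -1.7270, -1.9111, -0.8786,
      -1.5723, 2.1561, 0.5344,
      0.8553, 1.9404, 0.8776
    ), ncol = 3L, byrow = TRUE)
  ),
  ethylenediamine = list(
    elements = c("N", "C", "C", "N", "H", "H", "H", "H", "H", "H", "H", "H"),
    coords = matrix(c(
      1.8450, 0.0232, -0.0748,
      0.4651, -0.4481, -0.1526,
      -0.5419, 0.6983, 0.0497,
      -1.9293, 0.2383, -0.0199,
      2.4789, -0.7705, -0.1582,
      2.0175, 0.4314, 0.8435,
      0.3086, -1.2210, 0.6087,
      0.3063, -0.9130, -1.1320,
      -0.3807, 1.1697, 1.0258,
      -0.3894, 1.4714, -0.7119,
      -2.1015, -0.1729, -0.9369,
      -2.0787, -0.5069, 0.6586
    ), ncol = 3L, byrow = TRUE)
  )
)

#' Frozen toy molecule library
#'
#' Thirteen small molecules with frozen MMFF94-relaxed coordinates:
#' amines, acids, azoles, an S-heterocycle acid (biotin-like), a
#' bromoarene and ethane as a no-site negative control. Coordinates are
#' identical across calls; bonds are perceived from distances.
#'
#' @return named list of `molecule` objects.
#' @export
toy_library <- function() {
  out <- lapply(names(.TOY_COORDS), function(nm) {
    d <- .TOY_COORDS[[nm]]
    molecule(d$elements, d$coords, 0L, NULL, nm)
  })
  names(out) <- names(.TOY_COORDS)
  out
}

#' Hand-verified titratable-site ground truth
#'
#' Expected output of [find_titratable_sites()] for every library molecule
#' and both ion modes, compiled by manual inspection of each structure.
#' Keys are `"<name>|protonation"` and `"<name>|deprotonation"`; values
#' are data.frames with `atom_index`, `element` and `acidic_h_index`
#' (NA for protonation).
#'
#' @return named list of site tables.
#' @export
expected_sites <- function() {
  site <- function(idx, el, h = NA_integer_) {
    data.frame(atom_index = as.integer(idx), element = el,
               acidic_h_index = as.integer(h), stringsAsFactors = FALSE)
  }
  none <- site(integer(0), character(0), integer(0))
  list(
    # water: the lone O both accepts and gives up a proton
    `water|protonation` = site(1L, "O"),
    `water|deprotonation` = site(1L, "O", 2L),
    `ammonia|protonation` = site(1L, "N"),
    `ammonia|deprotonation` = site(1L, "N", 2L),
    # ethane: negative control, no N or O
    `ethane|protonation` = none,
    `ethane|deprotonation` = none,
    # pyridine: ring N accepts; no acidic H anywhere
    `pyridine|protonation` = site(4L, "N"),
    `pyridine|deprotonation` = none,
    # acetic acid: carbonyl O and hydroxyl O accept; only O-H is acidic
    `acetic_acid|protonation` = site(c(3L, 4L), c("O", "O")),
    `acetic_acid|deprotonation` = site(4L, "O", 8L),
    # glycine: amine N + both carboxyl O accept; N-H and O-H are acidic
    `glycine|protonation` = site(c(1L, 4L, 5L), c("N", "O", "O")),
    `glycine|deprotonation` = site(c(1L, 5L), c("N", "O"), c(6L, 10L)),
    `ethanolamine|protonation` = site(c(1L, 4L), c("N", "O")),
    `ethanolamine|deprotonation` = site(c(1L, 4L), c("N", "O"), c(5L, 11L)),
    # imidazole: both ring N accept; only the pyrrole-type N-H is acidic
    `imidazole|protonation` = site(c(3L, 5L), c("N", "N")),
    `imidazole|deprotonation` = site(3L, "N", 8L),
    # formamide: amide N and carbonyl O both kept
    `formamide|protonation` = site(c(1L, 3L), c("N", "O")),
    `formamide|deprotonation` = site(1L, "N", 4L),
    # cysteine: S and S-H excluded (N/O chemistry only)
    `cysteine|protonation` = site(c(1L, 6L, 7L), c("N", "O", "O")),
    `cysteine|deprotonation` = site(c(1L, 7L), c("N", "O"), c(8L, 14L)),
    `thiolane_acid|protonation` = site(c(1L, 3L), c("O", "O")),
    `thiolane_acid|deprotonation` = site(1L, "O", 9L),
    `bromoaniline|protonation` = site(1L, "N"),
    `bromoaniline|deprotonation` = site(1L, "N", 9L),
    # ethylenediamine: the two amine N are graph-equivalent -> one site
    `ethylenediamine|protonation` = site(1L, "N"),
    `ethylenediamine|deprotonation` = site(1L, "N", 5L)
  )
}

#' Synthetic training-table specification
#'
#' Defines the generator's study conditions: how many systems, how many
#' candidate models per system, which features carry the planted linear
#' energy signal, and the label noise. The defaults plant the signal on
#' the CBA-COE distance with noise at 10% of the signal range.
#'
#' @param n_systems number of systems.
#' @param models_per_system integer range `c(lo, hi)` of models drawn per
#'   system.
#' @param planted_weights named numeric vector of per-feature energy
#'   coefficients (kcal/mol per feature unit); at least one nonzero.
#' @param noise_sd Gaussian label noise, kcal/mol.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_systems = 200L, models_per_system = c(4L, 8L),
                           planted_weights = c(dist_cba_coe = 2.0),
                           noise_sd = 2.0, seed = 1L) {
  stopifnot(noise_sd >= 0, any(planted_weights != 0),
            all(names(planted_weights) %in% feature_schema()))
  structure(list(n_systems = as.integer(n_systems),
                 models_per_system = as.integer(models_per_system),
                 planted_weights = planted_weights,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Physically plausible sampling spans for each descriptor.
.FEATURE_RANGES <- list(
  cba_polarizability = c(0.802, 1.100),  # O and N table values
  dist_cba_com = c(0, 10), dist_cba_coe = c(0, 10), dist_com_coe = c(0, 10),
  interaction_angle = c(0, 180), msa = c(50, 800),
  n_oxygen = c(0L, 6L), n_nitrogen = c(0L, 6L), n_halogen = c(0L, 6L),
  n_othergen = c(0L, 6L)
)

#' Generate a synthetic training table
#'
#' Per system, draws feature vectors uniformly from plausible physical
#' spans (distances 0-10 A, angle 0-180 degrees, MSA 50-800 A^2, counts
#' 0-6), computes a raw energy as the planted linear combination plus
#' Gaussian noise, and converts it to a relative-energy label by
#' subtracting the per-system minimum — emulating how RE labels are
#' computed across all modeled charge states of one system.
#'
#' @param spec a `synthetic_spec`.
#' @return training-table data.frame passing [validate_training_table()].
#' @export
synthetic_training_table <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  schema <- feature_schema()
  counts_feats <- c("n_oxygen", "n_nitrogen", "n_halogen", "n_othergen")
  rows <- vector("list", spec$n_systems)
  for (s in seq_len(spec$n_systems)) {
    m <- sample(seq(spec$models_per_system[1L], spec$models_per_system[2L]), 1L)
    feats <- sapply(schema, function(f) {
      rg <- .FEATURE_RANGES[[f]]
      if (f %in% counts_feats) {
        sample(seq(rg[1L], rg[2L]), m, replace = TRUE)
      } else if (f == "cba_polarizability") {
        sample(rg, m, replace = TRUE)
      } else {
        stats::runif(m, rg[1L], rg[2L])
      }
    })
    feats <- matrix(feats, nrow = m, dimnames = list(NULL, schema))
    w <- stats::setNames(numeric(length(schema)), schema)
    w[names(spec$planted_weights)] <- spec$planted_weights
    raw <- as.numeric(feats %*% w) + stats::rnorm(m, 0, spec$noise_sd)
    df <- as.data.frame(feats)
    df$re_label <- raw - min(raw)
    df$system_id <- sprintf("sys_%04d", s)
    rows[[s]] <- df
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  validate_training_table(tab)
  tab
}
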