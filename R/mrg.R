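# McIntyre-Richardson-Grill double-cable myelinated axon: bundled published
# geometric parameters with diameter interpolation, and fiber construction.

# Published MRG geometry vs. fiber diameter (um). Columns: fiber diameter,
# node/MYSA axolemma diameter, FLUT/STIN axolemma diameter, internode
# spacing, FLUT (paranode) length, number of myelin lamellae.
mrg_table <- function() {
  tibble::tribble(
    ~fiber_d, ~node_d, ~axon_d, ~deltax, ~flut_len, ~lamellae,
    5.7,      1.9,     3.4,     500,     35,        80,
    7.3,      2.4,     4.6,     750,     38,        100,
    8.7,      2.8,     5.8,     1000,    40,        110,
    10.0,     3.3,     6.9,     1150,    46,        120,
    11.5,     3.7,     8.1,     1250,    50,        130,
    12.8,     4.2,     9.2,     1350,    54,        135,
    14.0,     4.7,     10.4,    1400,    56,        140,
    15.0,     5.0,     11.5,    1450,    58,        145,
    16.0,     5.5,     12.7,    1500,    60,        150
  )
}

# Fixed MRG constants (36 C reference; rate q10 bases handled at run time).
mrg_constants <- function() {
  list(
    node_len = 1, mysa_len = 3, n_stin = 6,
    rho_axial = 70,      # axoplasm + periaxonal resistivity, ohm cm
    cm = 2,              # axolemma capacitance, uF/cm^2
    g_node_leak = 0.007, e_node_leak = -90,
    g_mysa = 0.001, g_flut = 1e-4, g_stin = 1e-4, e_pas = -80,
    gnaf = 3.0, gnap = 0.01, gks = 0.08,  # S/cm^2
    ena = 50, ek = -90, v_rest = -80,
    c_myelin_lamella = 0.1, g_myelin_lamella = 0.001,  # per lamella membrane
    space_node = 0.002, space_mysa = 0.002,            # periaxonal width, um
    space_flut = 0.004, space_stin = 0.004
  )
}

#' Interpolated MRG geometric parameters for a fiber diameter
#'
#' Linear interpolation between the tabulated diameters (5.7-16 um); below
#' the smallest tabulated diameter each parameter follows a power law fit
#' through the two smallest rows (positive and monotone down to 2 um).
#'
#' @param diameter_um Fiber diameter, micrometres.
#' @return List of geometric parameters (diameters and lengths in um).
#' @export
mrg_parameters <- function(diameter_um) {
  if (diameter_um <= 0) nm_abort("INVALID_DIAMETER", "diameter must be > 0")
  tb <- mrg_table()
  interp_col <- function(col) {
    v <- tb[[col]]
    if (diameter_um >= tb$fiber_d[1]) {
      stats::approx(tb$fiber_d, v, diameter_um, rule = 2)$y
    } else {
      alpha <- log(v[2] / v[1]) / log(tb$fiber_d[2] / tb$fiber_d[1])
      v[1] * (diameter_um / tb$fiber_d[1])^alpha
    }
  }
  k <- mrg_constants()
  deltax <- interp_col("deltax")
  flut_len <- interp_col("flut_len")
  stin_len <- (deltax - k$node_len - 2 * k$mysa_len - 2 * flut_len) / k$n_stin
  if (stin_len <= 0) nm_abort("INVALID_DIAMETER", "diameter too small for the internode layout")
  list(fiber_d = diameter_um,
       node_d = interp_col("node_d"),
       axon_d = interp_col("axon_d"),
       deltax = deltax, flut_len = flut_len, stin_len = stin_len,
       lamellae = interp_col("lamellae"))
}

#' Build an MRG fiber compartment model
#'
#' The internode pattern node-MYSA-FLUT-STIN x6-FLUT-MYSA repeats along the
#' path; the middle node of Ranvier is aligned with `center_um` (the
#' longitudinal center of the nerve model). The usual working range is
#' 2-16 um; diameters outside it warn.
#'
#' @param diameter_um Fiber diameter.
#' @param path_length_mm Minimum fiber length; rounded up to a whole,
#'   even number of internodes.
#' @param center_um Longitudinal coordinate for the middle node.
#' @return Object of class `mrg_fiber` with a compartment tibble
#'   (`type`, `length_um`, `z_um` centers, `d_axon_um`, `d_fiber_um`),
#'   node indices, and the interpolated parameter set.
#' @export
build_mrg_fiber <- function(diameter_um, path_length_mm = 50, center_um = 25000) {
  if (diameter_um < 2 || diameter_um > 16) {
    warning(sprintf("fiber diameter %.2f um outside the 2-16 um working range",
                    diameter_um))
  }
  p <- mrg_parameters(diameter_um)
  k <- mrg_constants()
  n_inter <- max(4, ceiling(path_length_mm * 1000 / p$deltax))
  if (n_inter %% 2 == 1) n_inter <- n_inter + 1

  inter_types <- c("MYSA", "FLUT", rep("STIN", k$n_stin), "FLUT", "MYSA")
  inter_lens <- c(k$mysa_len, p$flut_len, rep(p$stin_len, k$n_stin),
                  p$flut_len, k$mysa_len)
  types <- "node"; lens <- k$node_len
  for (i in seq_len(n_inter)) {
    types <- c(types, inter_types, "node")
    lens <- c(lens, inter_lens, k$node_len)
  }
  edges <- c(0, cumsum(lens))
  z <- (edges[-1] + edges[-length(edges)]) / 2
  node_idx <- which(types == "node")
  mid_node <- node_idx[(length(node_idx) + 1) / 2]
  z <- z - z[mid_node] + center_um

  d_axon <- vapply(types, function(tp) switch(tp,
    node = p$node_d, MYSA = p$node_d, FLUT = p$axon_d, STIN = p$axon_d),
    numeric(1))
  comp <- tibble::tibble(
    type = types, length_um = lens, z_um = z,
    d_axon_um = unname(d_axon), d_fiber_um = p$fiber_d
  )
  structure(list(compartments = comp, node_idx = node_idx,
                 mid_node = mid_node, diameter_um = diameter_um,
                 params = p),
            class = "mrg_fiber")
}

#' @export
print.mrg_fiber <- function(x, ...) {
  cat(sprintf("<mrg_fiber> %.1f um, %d compartments (%d nodes), length %.1f mm\n",
              x$diameter_um, nrow(x$compartments), length(x$node_idx),
              sum(x$compartments$length_um) / 1000))
  invisible(x)
}

# Electrical assembly: per-compartment capacitances (uF), conductances (mS)
# and axial conductances (mS) in the mV/ms/uA unit system.
mrg_electrical <- function(fiber) {
  k <- mrg_constants()
  cmp <- fiber$compartments
  n <- nrow(cmp)
  # areas in cm^2 (um^2 -> cm^2 is 1e-8)
  area_ax <- pi * cmp$d_axon_um * cmp$length_um * 1e-8
  area_my <- pi * cmp$d_fiber_um * cmp$length_um * 1e-8
  is_node <- cmp$type == "node"
  nl <- fiber$params$lamellae

  cm <- k$cm * area_ax
  gpas <- numeric(n); epas <- numeric(n)
  gpas[is_node] <- k$g_node_leak * 1000 * area_ax[is_node]
  epas[is_node] <- k$e_node_leak
  for (tp in c("MYSA", "FLUT", "STIN")) {
    g0 <- switch(tp, MYSA = k$g_mysa, FLUT = k$g_flut, STIN = k$g_stin)
    sel <- cmp$type == tp
    gpas[sel] <- g0 * 1000 * area_ax[sel]
    epas[sel] <- k$e_pas
  }
  cmy <- (k$c_myelin_lamella / (2 * nl)) * area_my
  gmy <- (k$g_myelin_lamella / (2 * nl)) * 1000 * area_my
  # node: periaxonal space opens to the extracellular medium
  cmy[is_node] <- 0
  gmy[is_node] <- 1e3

  gnaf <- ifelse(is_node, k$gnaf * 1000 * area_ax, 0)
  gnap <- ifelse(is_node, k$gnap * 1000 * area_ax, 0)
  gks <- ifelse(is_node, k$gks * 1000 * area_ax, 0)

  # axial conductances between consecutive compartment centers
  len_cm <- cmp$length_um * 1e-4
  a_cross <- pi * (cmp$d_axon_um * 1e-4)^2 / 4
  r_half <- k$rho_axial * (len_cm / 2) / a_cross          # ohm
  gax <- 1000 / (r_half[-n] + r_half[-1])                 # mS
  space <- vapply(cmp$type, function(tp) switch(tp,
    node = k$space_node, MYSA = k$space_mysa,
    FLUT = k$space_flut, STIN = k$space_stin), numeric(1))
  a_peri <- pi * (cmp$d_axon_um * 1e-4) * (space * 1e-4)
  rp_half <- k$rho_axial * (len_cm / 2) / a_peri
  gp <- 1000 / (rp_half[-n] + rp_half[-1])

  list(cm = cm, gpas = gpas, epas = epas, cmy = cmy, gmy = gmy,
       is_node = as.integer(is_node), gnaf = gnaf, gnap = gnap, gks = gks,
       gax = gax, gp = gp)
}
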