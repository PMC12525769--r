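#' Seeded TRES simulation presets
#'
#' Reference synthetic datasets emulating the bundle-shaped PBS
#' time-resolved emission experiments. All presets share the
#' PE -> PC -> AP cascade with total-decay lifetimes 70 ps / 165 ps /
#' 1.9 ns and a 100-ps-fwhm Gaussian IRF on the 4096-channel, 12.5-ns
#' axis. Quenched presets are mixtures of OCP-bound and unbound
#' particles; binding shortens the AP (terminal) lifetime:
#' \describe{
#'   \item{gvipbs_unquenched}{no quencher.}
#'   \item{gvipbs_alpha_quenched}{bound fraction 0.9, AP lifetime x 0.15
#'     (the fast, efficient quencher).}
#'   \item{gvipbs_beta_quenched}{bound fraction 0.5, AP lifetime x 0.35
#'     (slower, less efficient).}
#'   \item{gvipbs_dual_quenched}{both quenchers bind independently
#'     (Bliss composition of the bound fractions); doubly bound particles
#'     take the stronger (alpha) lifetime factor.}
#' }
#' The generator parameters are embedded in `metadata`, so recovery tests
#' are self-verifying.
#'
#' @param name Preset name (see above).
#' @param seed Integer RNG seed for the photon noise.
#' @param peak_counts Expected counts in the brightest bin of the
#'   unquenched reference (default 1e4); quenched presets share that
#'   acquisition's intensity scale, so their maxima fall below this.
#' @param noise If `FALSE`, return noiseless expected counts.
#' @return A `tres` dataset.
#' @export
make_tres_preset <- function(name, seed = 1L, peak_counts = 1e4, noise = TRUE) {
  valid <- c("gvipbs_unquenched", "gvipbs_alpha_quenched",
             "gvipbs_beta_quenched", "gvipbs_dual_quenched")
  if (!name %in% valid)
    stop_pbsq("unknown preset '", name, "'; valid presets: ",
              paste(valid, collapse = ", "))
  tau <- c(PE = 0.070, PC = 0.165, AP = 1.9)
  f_alpha <- 0.9;  shorten_alpha <- 0.15
  f_beta  <- 0.5;  shorten_beta  <- 0.35
  pops <- switch(name,
    gvipbs_unquenched = list(list(w = 1, ap = 1)),
    gvipbs_alpha_quenched = list(
      list(w = 1 - f_alpha, ap = 1),
      list(w = f_alpha, ap = shorten_alpha)),
    gvipbs_beta_quenched = list(
      list(w = 1 - f_beta, ap = 1),
      list(w = f_beta, ap = shorten_beta)),
    gvipbs_dual_quenched = list(
      list(w = (1 - f_alpha) * (1 - f_beta), ap = 1),
      list(w = f_alpha * (1 - f_beta), ap = shorten_alpha),
      list(w = (1 - f_alpha) * f_beta, ap = shorten_beta),
      # doubly bound: the stronger quencher sets the AP lifetime
      list(w = f_alpha * f_beta, ap = shorten_alpha)))
  axis <- time_axis()
  irf <- irf_model()
  spectra <- emission_spectra()
  mix_signal <- function(pp) {
    sig <- 0
    for (p in pp) {
      tl <- tau; tl["AP"] <- tau["AP"] * p$ap
      conc <- propagate(eet_cascade(lifetimes_ns = tl), axis)
      sig <- sig + p$w * tres_ideal(conc, spectra)
    }
    sig <- convolve_irf(sig, irf, axis)
    sig[sig < 0] <- 0
    sig
  }
  sig <- mix_signal(pops)
  # all presets share the unquenched acquisition's intensity scale, as in
  # matched measurements of the same sample before/after photoactivation
  ref_peak <- if (name == "gvipbs_unquenched") max(sig)
              else max(mix_signal(list(list(w = 1, ap = 1))))
  lifetimes_present <- sort(unique(c(tau[c("PE", "PC")],
                                     vapply(pops, function(p) tau[["AP"]] * p$ap, 0))))
  add_poisson(sig, axis, spectra$wavelengths_nm, peak_counts,
              seed = seed, noise = noise, reference_peak = ref_peak,
              metadata = list(
                preset = name,
                lifetimes_ns = unname(tau),
                populations = pops,
                lifetimes_present_ns = unname(lifetimes_present),
                irf_fwhm_ps = irf$fwhm_ps, irf_t0_ns = irf$t0_ns,
                transfer_frac = 0.9))
}

# planar 4-ring pseudo-bilin scaffold, ~20 atoms, mass centre at origin
toy_bilin_template <- function() {
  ring <- function(cx) {
    th <- 2 * pi * (0:4) / 5 + pi / 2
    data.frame(element = c("N", "C", "C", "C", "C"),
               x = cx + 1.1 * cos(th), y = 1.1 * sin(th), z = 0)
  }
  at <- rbind(ring(-4.5), ring(-1.5), ring(1.5), ring(4.5))
  at$ring <- rep(c("A", "B", "C", "D"), each = 5)
  at$mass <- element_masses(at$element)
  ctr <- mass_center_xyz(at)
  at$x <- at$x - ctr[1]; at$y <- at$y - ctr[2]; at$z <- at$z - ctr[3]
  at
}

#' Ring-atom index sets of the toy pseudo-bilin
#'
#' Atom-index subsets (A-D) matching [make_toy_structure()] residues, for
#' use with [coplanarity()].
#' @return Named list of integer index vectors.
#' @export
toy_ring_defs <- function() {
  r <- rep(c("A", "B", "C", "D"), each = 5)
  lapply(stats::setNames(nm = c("A", "B", "C", "D")), function(g) which(r == g))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed; uniform over O(3), det forced +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Write a toy coordinate file of pseudo-chromophores
#'
#' Places one rigid planar 4-ring pseudo-bilin residue (20 atoms, residue
#' name `BLN`) at each requested mass-center position, with a random
#' (seeded) rigid rotation per site and optional Gaussian jitter of the
#' centre. Chains are assigned one per group, so the file round-trips
#' through [harvest_chromophores()] with a matching group map. The
#' geometry is synthetic: it exercises the distance and coplanarity
#' machinery but does not mimic real bilin atom names.
#'
#' @param layout Data frame with columns `group`, `bilin_type`, `x`, `y`,
#'   `z` (target mass centres, angstrom).
#' @param path Output PDB path.
#' @param jitter_A Gaussian s.d. applied to each site centre (default 0).
#' @param seed RNG seed for rotations and jitter.
#' @return Invisible list with `path`, `group_map` (chain -> group) and
#'   `ligand_map` suitable for [harvest_chromophores()].
#' @export
make_toy_structure <- function(layout, path, jitter_A = 0, seed = 1L) {
  layout <- as.data.frame(layout)
  if (!nrow(layout)) stop_pbsq("layout must contain at least one site")
  stopifnot(all(c("group", "x", "y", "z") %in% names(layout)))
  groups <- unique(layout$group)
  if (length(groups) > 26) stop_pbsq("at most 26 groups (one chain letter each)")
  chain_of <- stats::setNames(LETTERS[seq_along(groups)], groups)
  tmpl <- toy_bilin_template()
  with_seed(seed, {
    xyz <- NULL; resno <- NULL; chain <- NULL; elety <- NULL; elesy <- NULL
    per_chain <- stats::setNames(integer(length(groups)), groups)
    for (i in seq_len(nrow(layout))) {
      g <- layout$group[i]
      per_chain[g] <- per_chain[g] + 1L
      rot <- random_rotation()
      ctr <- c(layout$x[i], layout$y[i], layout$z[i])
      if (jitter_A > 0) ctr <- ctr + stats::rnorm(3, 0, jitter_A)
      pos <- t(rot %*% t(as.matrix(tmpl[, c("x", "y", "z")]))) +
        matrix(ctr, nrow(tmpl), 3, byrow = TRUE)
      xyz <- c(xyz, as.vector(t(pos)))
      resno <- c(resno, rep(per_chain[g], nrow(tmpl)))
      chain <- c(chain, rep(chain_of[[g]], nrow(tmpl)))
      elety <- c(elety, paste0(tmpl$element, seq_len(nrow(tmpl))))
      elesy <- c(elesy, tmpl$element)
    }
    n <- length(elesy)
    bio3d::write.pdb(file = path, xyz = round(xyz, 3), type = rep("HETATM", n),
                     resno = resno, resid = rep("BLN", n),
                     eleno = seq_len(n), elety = elety, chain = chain,
                     elesy = elesy)
  })
  invisible(list(path = path,
                 group_map = stats::setNames(groups, chain_of[groups]),
                 ligand_map = c(BLN = "unknown")))
}

#' Seeded temperature-series photocycle fixture
#'
#' Wraps [simulate_photocycle_series()] with a fixed default activation
#' energy of 60 kJ/mol (a fixture choice in the physiological range for
#' OCP recovery, not a measured value) and `lnA` chosen so that the 25 C
#' rate constant is 0.01 s^-1.
#'
#' @param Ea_kJmol Activation energy, kJ/mol (default 60).
#' @param temps_C Temperatures (default 5-25 C in 5 C steps).
#' @param noise_sd Multiplicative noise s.d. (default 0).
#' @param seed RNG seed.
#' @return As [simulate_photocycle_series()], with `Ea_kJmol` and `lnA`
#'   attached as attributes.
#' @export
make_photocycle_preset <- function(Ea_kJmol = 60, temps_C = c(5, 10, 15, 20, 25),
                                   noise_sd = 0, seed = 1L) {
  lnA <- log(0.01) + Ea_kJmol * 1000 / (8.314 * 298.15)
  out <- simulate_photocycle_series(Ea_kJmol, lnA, temps_C,
                                    noise_sd = noise_sd, seed = seed)
  attr(out, "Ea_kJmol") <- Ea_kJmol
  attr(out, "lnA") <- lnA
  out
}
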