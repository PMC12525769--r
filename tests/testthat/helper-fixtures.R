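# shared fixture builders: small problem sizes keep the suite fast while
# exercising the same code paths as the full-size presets

small_axis <- function(n = 1024L, window = 12.5) time_axis(n, window)

small_spectra <- function() emission_spectra(wavelengths_nm = seq(560, 700, by = 4))

# mixture of quenched/unquenched cascades on an arbitrary axis; mirrors the
# construction of make_tres_preset at reduced size
sim_mixture <- function(pops, axis = small_axis(), spectra = small_spectra(),
                        irf = irf_model(), peak = 1e4, seed = NULL,
                        noise = FALSE, ref_pops = NULL,
                        tau = c(PE = 0.070, PC = 0.165, AP = 1.9)) {
  mix <- function(pp) {
    sig <- 0
    for (p in pp) {
      tl <- tau; tl["AP"] <- tau["AP"] * p$ap
      sig <- sig + p$w * tres_ideal(propagate(eet_cascade(lifetimes_ns = tl), axis),
                                    spectra)
    }
    s <- convolve_irf(sig, irf, axis)
    s[s < 0] <- 0
    s
  }
  sig <- mix(pops)
  ref <- if (is.null(ref_pops)) max(sig) else max(mix(ref_pops))
  add_poisson(sig, axis, spectra$wavelengths_nm, peak, seed = seed,
              noise = noise, reference_peak = ref,
              metadata = list(populations = pops))
}

pops_unq <- list(list(w = 1, ap = 1))
pops_mixture <- function(frac_bound, shorten)
  list(list(w = 1 - frac_bound, ap = 1), list(w = frac_bound, ap = shorten))

# distinct lifetimes present in a mixture (total-decay eigenvalues)
mixture_lifetimes <- function(pops, tau = c(0.070, 0.165, 1.9))
  sort(unique(c(tau[1:2], vapply(pops, function(p) tau[3] * p$ap, 0))))

# DAS via linear amplitude solve at known lifetimes (no nonlinear search)
fit_at_known_lifetimes <- function(data, lifetimes, irf = irf_model()) {
  B <- reconvolution_basis(lifetimes, irf, data$axis)
  A <- solve_amplitudes(data, B)
  structure(list(lifetimes_ns = lifetimes, das = A,
                 wavelengths_nm = data$wavelengths_nm,
                 n_components = length(lifetimes)),
            class = "das_fit")
}

# chromophore site built directly from coordinates (unit masses by default)
site_from_xyz <- function(xyz, id = "s1", group = "unassigned", mass = 1) {
  xyz <- matrix(xyz, ncol = 3)
  chromophore_site(site_id = id, atoms = data.frame(
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = rep_len(mass, nrow(xyz))), group = group)
}

point_sites <- function(centers, groups = NULL, ids = NULL) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  groups <- groups %||% rep("unassigned", n)
  ids <- ids %||% sprintf("s%02d", seq_len(n))
  lapply(seq_len(n), function(i)
    site_from_xyz(centers[i, ], id = ids[i], group = groups[i]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
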