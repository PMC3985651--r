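# Small architectures with the search confined to the modelled segment
# (genome_length = 1), so kinetics are fast enough for statistical tests.

mk_single <- function(E_eff = -6, n = 1, M = 2000, L = 20, lambda = 0.33,
                      ...) {
  build_architecture(
    data.frame(site_id = "s1", tf = "A", start = (M - L) / 2, length = L,
               energy = E_eff / lambda, stringsAsFactors = FALSE),
    list(A = tf_species("A", n, genome_length = 1, affinity_scale = lambda,
                        ...)),
    M = M)
}

mk_pair <- function(gap, same_tf = FALSE, E_eff = -6, n1 = 1, n2 = 1,
                    M = 2000, L = 20, lambda = 0.33) {
  s1 <- round((M - 2 * L - max(gap, 0)) / 2)
  st <- data.frame(site_id = c("s1", "s2"), tf = c("A", if (same_tf) "A"
                                                   else "B"),
                   start = c(s1, s1 + L + gap), length = L,
                   energy = E_eff / lambda, stringsAsFactors = FALSE)
  species <- list(A = tf_species("A", n1, genome_length = 1,
                                 affinity_scale = lambda))
  if (!same_tf)
    species$B <- tf_species("B", n2, genome_length = 1,
                            affinity_scale = lambda)
  build_architecture(st, species, M = M)
}

analytic_kon <- function(arch, site, config = NULL, mode = "facilitated") {
  i <- match(site, arch$sites$site_id)
  sp <- arch$species[[arch$sites$tf[i]]]
  occ <- fdlogic:::normalize_config(arch, config)
  bound <- sum(occ & arch$sites$tf == arch$sites$tf[i])
  binding_propensity(
    search_params(sp$copy_number - bound, arch$M, sp),
    effective_region(arch, occ, site, mode = mode), sp)
}
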