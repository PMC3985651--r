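test_that("effective sliding region reproduces the pinned worked cases", {
  # isolated site: catchment is one sliding length
  iso <- mk_single()
  expect_equal(effective_region(iso, NULL, "s1")$s_eff, 90)

  # occupied barrier 1 bp away: far side 35 + site 20 + 1 bp approach
  bar <- mk_pair(1)
  er <- effective_region(bar, c(s2 = TRUE), "s1")
  expect_equal(er$s_eff, 56)

  # two empty 20-bp cluster sites 1 bp apart: the empty partner is a trap
  # and claims half of the gap
  cl <- mk_pair(1, same_tf = TRUE, n1 = 2)
  expect_equal(effective_region(cl, NULL, "s1")$s_eff, 55.5)

  # s_eff shrinks monotonically as an occupied barrier approaches
  vals <- vapply(c(45, 30, 20, 10, 5, 1, 0), function(d)
    effective_region(mk_pair(d), c(s2 = TRUE), "s1")$s_eff, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[length(vals)], 55)
})

test_that("walk region is truncated by occupied barriers, not empty clusters", {
  bar <- mk_pair(1)
  wr_bar <- effective_region(bar, c(s1 = TRUE, s2 = TRUE), "s1")$walk_region
  iso <- mk_single()
  wr_iso <- effective_region(iso, c(s1 = TRUE), "s1")$walk_region
  expect_equal(diff(wr_iso), 90)
  expect_equal(diff(wr_bar), 56)
  # empty same-TF partner does not restrict the walk
  cl <- mk_pair(1, same_tf = TRUE, n1 = 2)
  expect_equal(diff(effective_region(cl, c(s1 = TRUE), "s1")$walk_region), 90)
})

test_that("3d-only mode removes the sliding contribution entirely", {
  for (d in c(0, 100)) {
    a <- mk_pair(d)
    expect_equal(effective_region(a, c(s2 = TRUE), "s1",
                                  mode = "3d_only")$s_eff, 20)
  }
})

test_that("binding propensity implements the geometric search model", {
  sp <- tf_species("X", 1, t_walk = 9e-3, t_3d = 1e-3, genome_length = 1)
  params <- search_params(1, M = 900, species = sp)
  expect_equal(binding_propensity(params, list(s_eff = 90), sp), 10)

  # oracle: mean waiting time of a simulated geometric search,
  # Bernoulli(90/900) rounds of 0.01 s, inverted
  set.seed(2)
  rounds <- stats::rgeom(40000, prob = 90 / 900) + 1
  mc <- 1 / mean(rounds * 0.01)
  expect_lt(abs(mc - 10) / 10, 0.02)

  # linear in the number of searching molecules
  p2 <- search_params(2, M = 900, species = sp)
  expect_equal(binding_propensity(p2, list(s_eff = 90), sp),
               2 * binding_propensity(params, list(s_eff = 90), sp))
  expect_equal(binding_propensity(search_params(0, 900, sp),
                                  list(s_eff = 90), sp), 0)
  expect_error(binding_propensity(params, list(s_eff = 1000), sp), "s_eff")
})

test_that("unbinding propensity follows the restricted Boltzmann walk", {
  # independent transcription of the formula on a small landscape:
  # site of 20 bp at effective depth -6 kT inside a 90+20 bp walk region
  a <- mk_single(E_eff = -6)
  k <- unbinding_propensity(a, c(s1 = TRUE), "s1")
  sp <- a$species$A
  W <- 20 + 2 * 35   # site plus the per-side reach: the isolated catchment
  S <- (W - 20) + 20 * exp(6)
  expect_equal(k, W / (sp$t_walk * S))

  # stronger target energy -> strictly lower propensity
  k_strong <- unbinding_propensity(mk_single(E_eff = -12), c(s1 = TRUE), "s1")
  expect_lt(k_strong, k)

  # occupied barrier restricts the walk -> lower propensity
  k_bar <- unbinding_propensity(mk_pair(1), c(s1 = TRUE, s2 = TRUE), "s1")
  expect_lt(k_bar, k)

  # empty cluster partner adds a second well -> lower propensity
  k_cl <- unbinding_propensity(mk_pair(1, same_tf = TRUE, n1 = 2),
                               c(s1 = TRUE), "s1")
  expect_lt(k_cl, k)
  expect_error(unbinding_propensity(a, NULL, "s1"), "state error")
})

test_that("relocation time is the mean first-passage of the 1D walk", {
  sp <- tf_species("A", 1)
  delta <- step_time(sp)
  # flat landscape closed form d(d+1)*delta
  for (d in c(1, 3, 10)) {
    expect_equal(relocation_time(d, sp), delta * d * (d + 1))
  }
  # Monte-Carlo oracle: lazy-reflecting walk, absorbing at d
  mc_steps <- function(d, nsim, seed) {
    set.seed(seed)
    mean(vapply(seq_len(nsim), function(i) {
      pos <- 0L; steps <- 0L
      while (pos < d) {
        steps <- steps + 1L
        mv <- sample(c(-1L, 1L), 1)
        pos <- max(pos + mv, 0L)
        if (pos == 0L && mv == -1L) pos <- 0L
      }
      steps
    }, numeric(1)))
  }
  m3 <- mc_steps(3, 4000, 7); m6 <- mc_steps(6, 4000, 8)
  expect_lt(abs(m3 * delta - relocation_time(3, sp)) /
              relocation_time(3, sp), 0.1)
  expect_lt(abs((m6 / m3) -
                  relocation_time(6, sp) / relocation_time(3, sp)), 0.45)
  # monotone in distance; propensity is the reciprocal
  expect_gt(relocation_propensity(2, sp), relocation_propensity(5, sp))
  expect_equal(relocation_propensity(4, sp) * relocation_time(4, sp), 1)
  # a deep source well slows relocation (escape included)
  t_well <- relocation_time(3, sp, source_length = 20, source_energy = -20)
  expect_gt(t_well, relocation_time(3, sp))
  expect_error(relocation_time(0, sp), "d must be")
})

test_that("transition tables enumerate exactly the legal reactions", {
  aba <- from_pattern("ABA")
  tr <- build_transitions(aba, NULL)
  expect_equal(sort(tr$kind), c("bind", "bind", "bind"))

  # AABAA with the first A bound: all sites bindable (no steric overlap at
  # gap 0), one unbind, one relocation to the adjacent empty A only
  aabaa <- from_pattern("AABAA")
  occ <- stats::setNames(c(TRUE, FALSE, FALSE, FALSE, FALSE),
                         aabaa$sites$site_id)
  tr <- build_transitions(aabaa, occ)
  expect_equal(as.integer(table(tr$kind)[c("bind", "relocate", "unbind")]),
               c(4L, 1L, 1L))
  expect_equal(tr$dest[tr$kind == "relocate"], "a2")

  # brute force over every configuration: reaction counts follow the rules
  cfgs <- enumerate_configurations(aabaa)
  st <- aabaa$sites
  for (r in seq_len(nrow(cfgs))) {
    occ <- cfgs[r, ]
    tr <- build_transitions(aabaa, occ)
    expect_true(all(tr$propensity > 0) && all(is.finite(tr$propensity)))
    n_bound_A <- sum(occ & st$tf == "A")
    exp_bind <- sum(!occ & (st$tf == "B" | n_bound_A < 10))
    expect_equal(sum(tr$kind == "bind"), exp_bind)
    expect_equal(sum(tr$kind == "unbind"), sum(occ))
    # relocations: bound A with adjacent-in-cluster empty A, first reached
    exp_rel <- 0
    a_idx <- which(st$tf == "A")
    for (i in which(occ)) {
      if (st$tf[i] != "A") next
      for (j in a_idx) {
        if (occ[j] || j == i) next
        gap <- abs(st$start[j] - st$start[i]) - 20
        if (gap >= 45) next
        between <- seq(min(i, j) + 1, length.out = max(i, j) - min(i, j) - 1)
        if (length(between) && any(occ[between] |
                                   st$tf[between] == "A")) next
        exp_rel <- exp_rel + 1
      }
    }
    expect_equal(sum(tr$kind == "relocate"), exp_rel)
  }
})

test_that("3d-only transition tables ignore spacing and never relocate", {
  for (d in c(0, 100)) {
    a <- mk_pair(d, n1 = 1, n2 = 1)
    tr <- build_transitions(a, c(s1 = TRUE), mode = "3d_only")
    expect_false(any(tr$kind == "relocate"))
    kb <- tr$propensity[tr$kind == "bind"]
    expect_equal(kb, analytic_kon(a, "s2", c(s1 = TRUE), mode = "3d_only"))
  }
  p0 <- build_transitions(mk_pair(0), c(s1 = TRUE), mode = "3d_only")
  p100 <- build_transitions(mk_pair(100), c(s1 = TRUE), mode = "3d_only")
  expect_equal(p0$propensity, p100$propensity)
})

test_that("all fixture architectures give finite non-negative propensities", {
  for (nm in c("switch5", "barrier_0", "cluster_low", "ABA_close", "AABAA",
               "AA_B_AA", "ABA_doubled")) {
    arch <- make_fixture(nm)
    cfgs <- enumerate_configurations(arch)
    for (r in seq_len(nrow(cfgs))) {
      tr <- build_transitions(arch, cfgs[r, ])
      expect_true(all(is.finite(tr$propensity) & tr$propensity >= 0))
    }
  }
})
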