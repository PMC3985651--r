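test_that("architectures are validated, sorted and carry their species", {
  sp <- list(A = tf_species("A", 10), B = tf_species("B", 10))
  st <- data.frame(site_id = c("a2", "b1", "a1"), tf = c("A", "B", "A"),
                   start = c(240, 120, 0), length = 20, energy = -30)
  arch <- build_architecture(st, sp, M = 400)
  expect_equal(arch$sites$site_id, c("a1", "b1", "a2"))
  expect_equal(diff(arch$sites$start), c(120, 120))
  rel <- classify_pairs(arch)
  expect_equal(rel$gap[rel$site_a == "a1" & rel$site_b == "b1"], 100)

  expect_error(build_architecture(st, sp, M = 250), "coordinate")
  expect_error(build_architecture(st, sp["A"], M = 400), "reference")
  expect_error(build_architecture(st, sp, M = 0), "positive")
  st2 <- st; st2$site_id <- c("x", "x", "y")
  expect_error(build_architecture(st2, sp, M = 400), "duplicate")

  empty <- build_architecture(st[0, ], sp, M = 100)
  expect_equal(nrow(enumerate_configurations(empty)), 1L)
})

test_that("pattern strings produce the documented geometry", {
  a <- from_pattern("ABA", site_length = 20, gap = 0, flank = 500)
  expect_equal(a$sites$start, c(500, 520, 540))
  expect_equal(a$M, 1060)

  b <- from_pattern("AA-B-AA", site_length = 20, gap = 0, flank = 500)
  expect_equal(b$sites$start, c(500, 520, 640, 760, 780))
  rel <- classify_pairs(b)
  aa <- rel[rel$site_a == "a1" & rel$site_b == "a2", ]
  expect_equal(aa$relation, "cluster")
  expect_equal(aa$gap, 0)
  expect_equal(rel$gap[rel$site_a == "a2" & rel$site_b == "b1"], 100)

  cde <- from_pattern("ABCDE")
  rel <- classify_pairs(cde)
  adj <- rel[abs(match(rel$site_b, cde$sites$site_id) -
                   match(rel$site_a, cde$sites$site_id)) == 1, ]
  expect_true(all(adj$relation == "barrier" & adj$gap == 0))

  expect_error(from_pattern(""), "non-empty")
  expect_error(from_pattern("A!B"), "letters")
  expect_error(from_pattern("AB", gap = -3), "gap")
})

test_that("pairwise classification follows the spacing rules", {
  sw <- mk_pair(-5)
  expect_equal(classify_pairs(sw)$relation, "switch")
  expect_equal(classify_pairs(sw)$gap, -5)

  cl <- mk_pair(1, same_tf = TRUE)
  expect_equal(classify_pairs(cl)$relation, "cluster")

  far <- mk_pair(120)
  expect_equal(classify_pairs(far)$relation, "independent")

  # brute-force threshold rule over a gap sweep, both TF identities
  for (gap in seq(0, 200, by = 10)) {
    for (same in c(TRUE, FALSE)) {
      got <- classify_pairs(mk_pair(gap, same_tf = same))$relation
      want <- if (same) {
        if (gap < 45) "cluster" else "independent"
      } else if (gap < 45) "barrier" else "independent"
      expect_equal(got, want, info = sprintf("gap=%d same=%d", gap, same))
    }
  }
  # census convention
  expect_equal(classify_pairs(mk_pair(20), barrier_threshold = 10)$relation,
               "independent")
  expect_equal(classify_pairs(mk_pair(5), barrier_threshold = 10)$relation,
               "barrier")
  expect_equal(nrow(classify_pairs(mk_single())), 0L)
})

test_that("classification is invariant under translation", {
  sp <- list(A = tf_species("A", 5), B = tf_species("B", 5))
  st <- data.frame(site_id = c("x", "y", "z"), tf = c("A", "B", "A"),
                   start = c(10, 25, 60), length = c(20, 20, 20),
                   energy = -30)
  r1 <- classify_pairs(build_architecture(st, sp, M = 300))
  st$start <- st$start + 1000
  r2 <- classify_pairs(build_architecture(st, sp, M = 1300))
  expect_equal(r1, r2)
})

test_that("nomenclature strings render overlap, adjacency and far spacers", {
  expect_equal(architecture_string(from_pattern("ABA")), "ABA")
  expect_equal(architecture_string(from_pattern("AA-B-AA")), "AA-B-AA")
  expect_equal(architecture_string(mk_pair(-5, same_tf = TRUE)), "A/A")
  expect_equal(architecture_string(mk_pair(-5)), "A/B")

  # letters are assigned by first appearance left to right
  sp <- list(Z = tf_species("Z", 1), Q = tf_species("Q", 1))
  st <- data.frame(site_id = c("s1", "s2"), tf = c("Z", "Q"),
                   start = c(0, 30), length = 20, energy = -30)
  expect_equal(architecture_string(build_architecture(st, sp, M = 100)),
               "AB")

  # identifier extension past 26 species
  nm <- paste0("tf", 1:27)
  sp <- stats::setNames(lapply(nm, tf_species, copy_number = 1), nm)
  st <- data.frame(site_id = paste0("s", 1:27), tf = nm,
                   start = seq(0, by = 200, length.out = 27), length = 20,
                   energy = -30)
  s <- architecture_string(build_architecture(st, sp, M = 6000))
  expect_match(s, "A1$")
})

test_that("pattern round-trips through the nomenclature", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    letters_part <- sample(c("A", "B", "C"), n, replace = TRUE)
    # canonicalize: the nomenclature assigns letters by first appearance
    letters_part <- LETTERS[match(letters_part, unique(letters_part))]
    seps <- sample(c("", "-"), n - 1, replace = TRUE)
    pat <- paste0(letters_part[1],
                  paste0(seps, letters_part[-1], collapse = ""))
    expect_equal(architecture_string(from_pattern(pat)), pat, info = pat)
  }
})

test_that("configuration space matches brute-force enumeration", {
  # 2 far sites, ample copies
  expect_equal(nrow(enumerate_configurations(mk_pair(200, n1 = 5, n2 = 5))),
               4L)
  # switch: overlap excludes double occupancy
  expect_equal(nrow(enumerate_configurations(mk_pair(-5, n1 = 5, n2 = 5))),
               3L)
  # copy-number cap: one TF with 1 copy owning two of three far sites
  sp <- list(A = tf_species("A", 1), B = tf_species("B", 1))
  st <- data.frame(site_id = c("a1", "b1", "a2"), tf = c("A", "B", "A"),
                   start = c(0, 200, 400), length = 20, energy = -30)
  arch <- build_architecture(st, sp, M = 600)
  expect_equal(nrow(enumerate_configurations(arch)), 6L)

  # independent recount for random architectures with <= 6 sites
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    tfs <- sample(c("A", "B"), n, replace = TRUE)
    starts <- sort(sample(seq(0, 400, by = 5), n))
    sp <- list(A = tf_species("A", sample(1:2, 1)),
               B = tf_species("B", sample(1:2, 1)))
    st <- data.frame(site_id = paste0("s", 1:n), tf = tfs, start = starts,
                     length = 20, energy = -30)
    arch <- build_architecture(st, sp, M = 600)
    count <- 0
    for (m in 0:(2^n - 1)) {
      occ <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
      ok <- TRUE
      idx <- which(occ)
      if (length(idx) > 1) {
        for (a in idx) for (b in idx) if (a < b &&
            starts[b] < starts[a] + 20) ok <- FALSE
      }
      for (tf in c("A", "B")) {
        if (sum(occ & tfs == tf) > sp[[tf]]$copy_number) ok <- FALSE
      }
      count <- count + ok
    }
    expect_equal(nrow(enumerate_configurations(arch)), count)
  }

  big <- data.frame(site_id = paste0("s", 1:21), tf = "A",
                    start = seq(0, by = 50, length.out = 21), length = 20,
                    energy = -30)
  arch21 <- build_architecture(big, list(A = tf_species("A", 21)), M = 2000)
  expect_error(enumerate_configurations(arch21), "capacity")
})

test_that("species invariants are enforced", {
  expect_error(tf_species("A", -1), "copy_number")
  expect_error(tf_species("A", 1, sliding_length = 0), "sliding_length")
  expect_error(tf_species("A", 1, t_walk = 0), "t_walk")
  expect_error(tf_species("A", 1, affinity_scale = 0), "affinity_scale")
  # occupancy invariants
  arch <- mk_pair(-5, n1 = 5, n2 = 5)
  expect_false(valid_configuration(arch, c(TRUE, TRUE)))
  expect_true(valid_configuration(arch, c(TRUE, FALSE)))
  one_copy <- mk_pair(200, same_tf = TRUE, n1 = 1)
  expect_false(valid_configuration(one_copy, c(TRUE, TRUE)))
})
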