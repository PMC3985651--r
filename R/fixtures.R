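# Reference promoter setups used throughout the package's analyses.
#
# The default binding energy (kT) is chosen so that the *effective* depth of
# a strong site after affinity scaling (0.33) is -10 kT, which under the
# lacI-derived search parameters reproduces the far-spaced double-barrier
# benchmark (~1600 s to the AND configuration). See the methods vignette
# ("Parameter choices").
fd_default_energy <- function() -10 / 0.33

#' Construct a named reference architecture
#'
#' Registry of the promoter setups the package's ensemble analyses are built
#' around:
#' * `switch5` — two different-TF sites overlapping by 5 bp, 10 copies each.
#' * `barrier_0`, `barrier_5`, `barrier_10`, `barrier_45`, `barrier_100` —
#'   different-TF pair at the given gap; focal TF 1 copy, neighbour 10.
#' * `cluster_low` / `cluster_high` — same-TF pair overlapping by 5 bp with
#'   10 / 100 copies.
#' * `ABA_far` / `ABA_close` — double-sided barrier, outer TF 2 copies with
#'   affinity scale 0.33, central TF 10 copies; gaps 100 / 0 bp.
#' * `AABAA`, `ABCDE`, `AA_B_AA` — the impulse comparison set (all gaps 0;
#'   `AA_B_AA` separates the clusters from the centre by 100 bp).
#' * `ABA_doubled` — ABA at gap 0 whose outer sites have twice the length
#'   and twice the binding strength (the cluster-mimicking double barrier).
#'
#' @param name Registry name.
#' @param energy Site binding energy in kT (before affinity scaling).
#' @param affinity_scale Energy scaling of every species.
#' @param copies Optional named integer vector overriding copy numbers by
#'   species letter, e.g. `c(A = 1, B = 10)`.
#' @param flank Non-specific flank in bp.
#' @return An `fd_architecture`.
#' @export
make_fixture <- function(name, energy = fd_default_energy(),
                         affinity_scale = 0.33, copies = NULL, flank = 500) {
  site_len <- 20
  sp <- function(nm, n) tf_species(nm, copy_number = n,
                                   affinity_scale = affinity_scale)
  pair <- function(tf2, gap, n1, n2, L1 = site_len) {
    s2 <- flank + L1 + gap
    st <- data.frame(site_id = c("s1", "s2"), tf = c("A", tf2),
                     start = c(flank, s2), length = c(L1, site_len),
                     energy = energy, stringsAsFactors = FALSE)
    species <- if (tf2 == "A") list(A = sp("A", n1)) else
      list(A = sp("A", n1), B = sp("B", n2))
    build_architecture(st, species, M = s2 + site_len + flank)
  }
  defaults <- function(letters_used, n) {
    out <- stats::setNames(rep(n, length(letters_used)), letters_used)
    if (!is.null(copies)) out[names(copies)] <- copies
    out
  }
  patt <- function(pattern, n = 10) {
    letters_used <- unique(strsplit(gsub("-", "", pattern), "")[[1]])
    nn <- defaults(letters_used, n)
    species <- lapply(letters_used, function(l) sp(l, nn[[l]]))
    names(species) <- letters_used
    from_pattern(pattern, site_length = site_len, gap = 0, flank = flank,
                 species = species, energy = energy)
  }
  cp <- function(def) if (is.null(copies)) def else {
    out <- def; out[names(copies)] <- copies; out
  }

  if (grepl("^barrier_", name)) {
    d <- as.numeric(sub("barrier_", "", name))
    if (!d %in% c(0, 5, 10, 45, 100))
      stop("registry error: unknown fixture ", name, call. = FALSE)
    nn <- cp(c(A = 1, B = 10))
    return(pair("B", gap = d, n1 = nn[["A"]], n2 = nn[["B"]]))
  }
  switch(name,
    switch5 = {
      nn <- cp(c(A = 10, B = 10))
      pair("B", gap = -5, n1 = nn[["A"]], n2 = nn[["B"]])
    },
    cluster_low = {
      nn <- cp(c(A = 10))
      pair("A", gap = -5, n1 = nn[["A"]], n2 = NA)
    },
    cluster_high = {
      nn <- cp(c(A = 100))
      pair("A", gap = -5, n1 = nn[["A"]], n2 = NA)
    },
    ABA_far = {
      nn <- cp(c(A = 2, B = 10))
      patt("A-B-A") |> override_copies(nn)
    },
    ABA_close = {
      nn <- cp(c(A = 2, B = 10))
      patt("ABA") |> override_copies(nn)
    },
    AABAA = patt("AABAA"),
    ABCDE = patt("ABCDE"),
    AA_B_AA = patt("AA-B-AA"),
    ABA_doubled = {
      nn <- cp(c(A = 10, B = 10))
      # outer sites: twice the length and twice the binding strength
      # (double the affinity constant, i.e. ln(2)/lambda deeper)
      e2 <- energy - log(2) / affinity_scale
      st <- data.frame(
        site_id = c("a1", "b1", "a2"), tf = c("A", "B", "A"),
        start = c(flank, flank + 40, flank + 60),
        length = c(40, site_len, 40),
        energy = c(e2, energy, e2),
        stringsAsFactors = FALSE)
      build_architecture(st, list(A = sp("A", nn[["A"]]),
                                  B = sp("B", nn[["B"]])),
                         M = flank + 100 + flank)
    },
    stop("registry error: unknown fixture ", name, call. = FALSE)
  )
}

override_copies <- function(arch, copies) {
  for (nm in intersect(names(copies), names(arch$species))) {
    arch$species[[nm]]$copy_number <- as.integer(copies[[nm]])
  }
  arch
}
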