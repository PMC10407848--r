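test_that("min_site_distance is the minimum over relay atom pairs", {
  tab <- default_relay_table()
  b <- relay_atoms(make_structure(at("OG", "SER", 2, c(3, 4, 0)))$atoms, tab)
  r <- min_site_distance(c(0, 0, 0), b)
  expect_equal(r$distance, 5.0)
  expect_equal(r$pair, c("anchor", "OG"))

  a2 <- relay_atoms(make_structure(
    at("OE1", "GLU", 1, c(0, 0, 0)),
    at("OE2", "GLU", 1, c(1, 0, 0)))$atoms, tab)
  b2 <- relay_atoms(make_structure(
    at("OD1", "ASP", 2, c(4, 0, 0)),
    at("OD2", "ASP", 2, c(9, 9, 9)))$atoms, tab)
  # brute force over the 4 pairs: OE2-OD1 on the x axis at 3.0 wins
  r2 <- min_site_distance(a2, b2)
  expect_equal(r2$distance, 3.0)
  expect_equal(r2$pair, c("OE2", "OD1"))
  # symmetry
  expect_equal(min_site_distance(b2, a2)$distance, 3.0)
  # coincident sites
  expect_equal(min_site_distance(a2, a2)$distance, 0.0)
})

test_that("candidates within the base cutoff need no extension", {
  s <- lone_glu_structure(3.4)
  sites <- relay_sites(s)
  cand <- find_candidates(c(0, 0, 0), sites, character(0), search_params())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$distance, 3.4)
  expect_equal(cand$cutoff_used, 5.0)
})

test_that("the cutoff extends adaptively and only up to dmax", {
  sites515 <- relay_sites(lone_glu_structure(5.15))
  cand <- find_candidates(c(0, 0, 0), sites515, character(0),
                          search_params())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$distance, 5.15)
  expect_lte(cand$cutoff_used, 5.3)
  expect_gt(cand$cutoff_used, 5.0)

  # beyond dmax: never found
  sites535 <- relay_sites(lone_glu_structure(5.35))
  expect_equal(nrow(find_candidates(c(0, 0, 0), sites535, character(0),
                                    search_params())), 0L)
  # with no extension allowed the 5.15 A candidate is out of reach
  p50 <- search_params(d0 = 5.0, dmax = 5.0)
  expect_equal(nrow(find_candidates(c(0, 0, 0), sites515, character(0),
                                    p50)), 0L)
  # boundary epsilon: a candidate just past dmax is never admitted
  sites_eps <- relay_sites(lone_glu_structure(5.35))
  expect_equal(nrow(find_candidates(c(0, 0, 0), sites_eps, character(0),
                                    search_params(dmax = 5.3))), 0L)
})

test_that("a spacing at 5.2 A is found after extension, as in the reference chain", {
  sites <- relay_sites(lone_glu_structure(5.2))
  cand <- find_candidates(c(0, 0, 0), sites, character(0), search_params())
  expect_equal(cand$distance, 5.2)
  expect_lte(cand$cutoff_used, 5.3)
})

test_that("candidate lists are sorted and ties break to lower residue number", {
  s <- make_structure(
    at("OG", "SER", 20, c(4, 0, 0)),
    at("OG", "SER", 7, c(0, 4, 0)),
    at("OE1", "GLU", 3, c(0, 0, 3)))
  cand <- find_candidates(c(0, 0, 0), relay_sites(s), character(0),
                          search_params())
  expect_equal(cand$distance, c(3, 4, 4))
  # the two 4.0 A sites order by resnum
  sites <- relay_sites(s)
  resnums <- vapply(sites[cand$index], `[[`, integer(1), "resnum")
  expect_equal(resnums, c(3, 7, 20))
})

test_that("the planted relay chain is recovered exactly, in order, to the surface", {
  g <- generate_relay_structure(relay_structure_spec(seed = 7))
  p <- trace_pathway(g$structure, g$ground_truth$anchor_selector)
  expect_equal(p$status, "reached_surface")
  expect_equal(nrow(p$steps), 4L)
  expect_equal(p$steps$resnum, g$ground_truth$relay_resnums)
  expect_equal(p$steps$distance, g$ground_truth$spacings, tolerance = 1e-9)
  expect_gte(p$terminal_rel_sasa, p$params$sasa_threshold)
  # determinism: identical inputs give identical results
  p2 <- trace_pathway(g$structure, g$ground_truth$anchor_selector)
  expect_identical(p, p2)
})

test_that("pathway degenerate cases carry the right status", {
  # only eligible residue beyond dmax
  p <- trace_pathway(lone_glu_structure(6.0), c(0, 0, 0))
  expect_equal(nrow(p$steps), 0L)
  expect_equal(p$status, "exhausted_cutoff")
  # no eligible sites at all
  ala <- make_structure(at("CB", "ALA", 1, c(3, 0, 0), element = "C"))
  p2 <- trace_pathway(ala, c(0, 0, 0))
  expect_equal(p2$status, "exhausted_cutoff")
  expect_equal(nrow(p2$steps), 0L)
  # an adjacent exposed glutamate ends the search after one step
  p3 <- trace_pathway(lone_glu_structure(2.5), c(0, 0, 0))
  expect_equal(p3$status, "reached_surface")
  expect_equal(nrow(p3$steps), 1L)
  expect_equal(p3$steps$distance, 2.5)
  # unresolvable anchor selector
  expect_error(trace_pathway(ala, atom_selector("A", 99, "XX")), "no atom")
})

test_that("enlarging the base cutoff never removes candidates (monotonicity)", {
  for (seed in 1:10) {
    r <- generate_random_structure(seed)
    sites <- relay_sites(r$structure)
    if (!length(sites)) next
    small <- find_candidates(r$anchor_point, sites, character(0),
                             search_params(d0 = 4.0, dmax = 5.3))
    big <- find_candidates(r$anchor_point, sites, character(0),
                           search_params(d0 = 5.0, dmax = 5.3))
    expect_true(all(small$index %in% big$index) ||
                  nrow(small) == 0, info = paste("seed", seed))
  }
})

test_that("greedy steps match brute-force distances and enumeration contains greedy paths", {
  for (seed in 1:20) {
    r <- generate_random_structure(seed)
    p <- trace_pathway(r$structure, r$anchor_point)
    if (nrow(p$steps) == 0) next
    prev <- r$anchor_point
    for (k in seq_len(nrow(p$steps))) {
      od <- oracle_min_dist(r$structure, prev, p$steps$resnum[k])
      expect_equal(p$steps$distance[k], od, tolerance = 1e-9,
                   info = sprintf("seed %d step %d", seed, k))
      expect_lte(p$steps$distance[k], p$params$dmax + 1e-9)
      prev <- c(chain = p$steps$chain[k], resnum = p$steps$resnum[k])
    }
    if (p$status == "reached_surface") {
      en <- enumerate_pathways(r$structure, r$anchor_point,
                               max_len = nrow(p$steps))
      expect_true(path_signature(p) %in% vapply(en, path_signature,
                                                character(1)),
                  info = paste("seed", seed))
    }
  }
})

test_that("enumeration handles symmetric exits, dead ends and the size guard", {
  # two equidistant single-step exposed exits are both enumerated
  s <- make_structure(
    at("OE1", "GLU", 1, c(4, 0, 0)),
    at("OE1", "GLU", 2, c(-4, 0, 0)))
  en <- enumerate_pathways(s, c(0, 0, 0), max_len = 1)
  expect_length(en, 2L)
  # one-step chains sort before longer ones
  expect_true(all(vapply(en, function(p) nrow(p$steps), integer(1)) == 1L))
  # nothing exposed reachable -> empty list
  g <- generate_relay_structure(relay_structure_spec(seed = 5,
                                                     expose_terminal = FALSE))
  en2 <- enumerate_pathways(g$structure, g$ground_truth$anchor_point,
                            max_len = 4)
  expect_length(en2, 0L)
  # guard on the number of eligible sites
  expect_error(enumerate_pathways(g$structure,
                                  g$ground_truth$anchor_point,
                                  max_sites = 2L), "too many")
})
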