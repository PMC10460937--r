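modes <- builtin_modes()

test_that("hand-checkable configurations: pair, triangle, star", {
  s <- semantics_config()
  # isolated C182 pair
  g <- graph_from_edges(2, cbind(1L, 2L))
  expect_identical(count_pattern(g, modes[["[L2]C182:C182"]], s), 1L)
  expect_identical(count_pattern(g, modes[["[L2]c182:c182"]], s), 1L)
  # isolated 3-clique of C182
  tri <- graph_from_edges(3, rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)))
  expect_identical(count_pattern(tri, modes[["[R3]c182:c182:c182:c182"]], s), 1L)
  expect_identical(count_pattern(tri, modes[["[L3]c182:c182:c182"]], s), 3L)
  expect_identical(count_pattern(tri, modes[["[L2]c182:c182"]], s), 3L)
  expect_identical(count_pattern(tri, modes[["[L2]C182:C182"]], s), 0L)
  # isolated K1,3 star of C182
  star <- graph_from_edges(4, cbind(1L, 2:4))
  expect_identical(count_pattern(star, modes[["[J4]C182:C182(:C182):C182"]], s), 1L)
  expect_identical(count_pattern(star, modes[["[J4]c182:c182(:c182):c182"]], s), 1L)
  expect_identical(count_pattern(star, modes[["[L3]c182:c182:c182"]], s), 3L)
  expect_identical(
    count_pattern(star, modes[["[J5]c182:(c182:)c182(:c182):c182"]], s), 0L)
  # mixed triangle {C182, C180, C182}
  nodes <- data.frame(node = 1:3, species = c("C182", "C180", "C182"),
                      molecule = 0:2)
  mixed <- contact_graph(nodes, rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)))
  expect_identical(count_pattern(mixed, modes[["[R3]c182:c180:c182:c182"]], s), 1L)
  expect_identical(count_pattern(mixed, modes[["[R3]c182:c182:c182:c182"]], s), 0L)
})

test_that("lowercase semantics: superset vs exclusive", {
  g <- graph_from_edges(2, cbind(1L, 2L))  # isolated pair
  sup <- semantics_config(lowercase_mode = "superset")
  exc <- semantics_config(lowercase_mode = "exclusive")
  expect_identical(count_pattern(g, modes[["[L2]c182:c182"]], sup), 1L)
  expect_identical(count_pattern(g, modes[["[L2]c182:c182"]], exc), 0L)
  # path of 3: middle node has an extra contact beyond each pair
  p3 <- graph_from_edges(3, rbind(c(1L, 2L), c(2L, 3L)))
  expect_identical(count_pattern(p3, modes[["[L2]c182:c182"]], sup), 2L)
  expect_identical(count_pattern(p3, modes[["[L2]c182:c182"]], exc), 0L)
  expect_identical(count_pattern(p3, modes[["[L2]C182:C182"]], sup), 0L)
})

test_that("case scope: global vs macro degree judging", {
  # C182-C182 pair where one endpoint also touches a C180
  nodes <- data.frame(node = 1:3, species = c("C182", "C182", "C180"),
                      molecule = 0:2)
  g <- contact_graph(nodes, rbind(c(1L, 2L), c(2L, 3L)))
  up <- modes[["[L2]C182:C182"]]
  expect_identical(count_pattern(g, up, semantics_config("global")), 0L)
  # within the ID_182_182 subgraph both endpoints have degree 1
  expect_identical(count_pattern(g, up, semantics_config("macro")), 1L)
})

test_that("closed-form identities hold on arbitrary graphs", {
  set.seed(5)
  for (rep in 1:10) {
    g <- random_mixed_graph(sample(15:45, 1), p = 0.15)
    for (sp in c("182", "180")) {
      sub <- macro_subgraph(g, paste0("ID_", sp, "_", sp))
      deg <- sub$degree
      lo <- function(t) parse_danai(gsub("X", sp, t))
      expect_equal(closed_form_count(g, lo("[L2]cX:cX")),
                       nrow(sub$edges))
      expect_equal(closed_form_count(g, lo("[L3]cX:cX:cX")),
                       as.integer(sum(choose(deg, 2))))
      expect_equal(closed_form_count(g, lo("[J4]cX:cX(:cX):cX")),
                       as.integer(sum(choose(deg, 3))))
      expect_equal(closed_form_count(g, lo("[J5]cX:(cX:)cX(:cX):cX")),
                       as.integer(sum(choose(deg, 4))))
      # closed form equals the census path
      for (t in c("[L2]cX:cX", "[L3]cX:cX:cX", "[J4]cX:cX(:cX):cX",
                  "[J5]cX:(cX:)cX(:cX):cX"))
        expect_identical(as.integer(closed_form_count(g, lo(t))),
                         count_pattern(g, lo(t)))
      # L3 >= 3 R3 within one species
      r3 <- count_pattern(g, lo("[R3]cX:cX:cX:cX"))
      l3 <- count_pattern(g, lo("[L3]cX:cX:cX"))
      expect_gte(l3, 3L * r3)
    }
  }
  expect_error(closed_form_count(random_mixed_graph(10),
                                 modes[["[L2]C182:C182"]]),
               "lowercase")
  expect_error(closed_form_count(random_mixed_graph(10),
                                 modes[["[R3]c182:c182:c182:c182"]]),
               "L2, L3, J4, J5")
})

test_that("known closed-form values: K4 and K1,4", {
  k4 <- graph_from_edges(4, t(utils::combn(4L, 2L)))
  expect_equal(closed_form_count(k4, modes[["[L3]c182:c182:c182"]]), 12L)
  expect_equal(closed_form_count(k4,
    modes[["[J4]c182:c182(:c182):c182"]]), 4L)
  expect_equal(closed_form_count(k4,
    modes[["[J5]c182:(c182:)c182(:c182):c182"]]), 0L)
  k14 <- graph_from_edges(5, cbind(1L, 2:5))
  expect_equal(closed_form_count(k14,
    modes[["[J5]c182:(c182:)c182(:c182):c182"]]), 1L)
  expect_equal(closed_form_count(k14,
    modes[["[J4]c182:c182(:c182):c182"]]), 4L)
  expect_equal(closed_form_count(k14, modes[["[L3]c182:c182:c182"]]), 6L)
  empty <- graph_from_edges(6, matrix(integer(0), 0, 2))
  for (t in c("[L2]c182:c182", "[L3]c182:c182:c182",
              "[J4]c182:c182(:c182):c182"))
    expect_equal(closed_form_count(empty, modes[[t]]), 0L)
})

test_that("count_modes: empty graph, key set, node-order invariance", {
  s <- semantics_config()
  empty <- graph_from_edges(4, matrix(integer(0), 0, 2))
  cm <- count_modes(empty, modes, s)
  expect_identical(names(cm), names(modes))
  expect_true(all(cm == 0L))
  set.seed(13)
  g <- random_mixed_graph(30, p = 0.12)
  cm1 <- count_modes(g, modes, s)
  # relabel nodes
  perm <- sample(30)
  inv <- order(perm)
  nodes2 <- g$nodes[perm, ]; nodes2$node <- 1:30
  e2 <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
  g2 <- contact_graph(nodes2, e2)
  expect_identical(count_modes(g2, modes, s), cm1)
})

test_that("uppercase counts never exceed their lowercase twins (superset)", {
  twins <- list(c("[L2]C182:C182", "[L2]c182:c182"),
                c("[L2]C180:C180", "[L2]c180:c180"),
                c("[L2]C182:C180", "[L2]c182:c180"),
                c("[J4]C182:C182(:C182):C182", "[J4]c182:c182(:c182):c182"),
                c("[J4]C180:C180(:C180):C180", "[J4]c180:c180(:c180):c180"))
  set.seed(17)
  s <- semantics_config()
  for (rep in 1:10) {
    g <- random_mixed_graph(sample(10:50, 1), p = 0.12)
    for (tw in twins)
      expect_lte(count_pattern(g, modes[[tw[1]]], s),
                 count_pattern(g, modes[[tw[2]]], s))
  }
})

test_that("lowercase L2 counts are monotone in the cutoff", {
  traj <- generate_liquid(n_molecules = 60L, box_length = 26, seed = 4L)
  fr <- traj$frames[[1]]
  ctr <- extract_centers(fr)
  s <- semantics_config()
  prev <- c(0L, 0L, 0L)
  for (cutoff in c(3.5, 4.5, 5.5)) {
    g <- build_contact_graph(ctr, fr$cell, cutoff = cutoff)
    now <- c(count_pattern(g, modes[["[L2]c182:c182"]], s),
             count_pattern(g, modes[["[L2]c180:c180"]], s),
             count_pattern(g, modes[["[L2]c182:c180"]], s))
    expect_true(all(now >= prev))
    prev <- now
  }
})

test_that("unsupported patterns are refused", {
  g <- random_mixed_graph(10)
  expect_error(count_pattern(g, parse_danai("[L4]c182:c182:c182:c182")),
               "unsupported")
  expect_error(count_pattern(g, parse_danai("[R4]c182:c182:c182:c182:c182")),
               "unsupported")
})
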