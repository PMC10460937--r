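test_that("the built-in mode set is the published 20-statement listing", {
  m <- builtin_modes()
  expect_length(m, 20L)
  macro <- attr(m, "macro")
  expect_identical(as.integer(table(macro)[c("ID_182_182", "ID_180_180",
                                             "ID_180_182")]),
                   c(7L, 7L, 6L))
  expect_true("[J4]C180:C180(:C180):C180" %in% names(m))
  expect_true("[R3]c180:c182:c180:c180" %in% names(m))
  # every statement survives parse -> format byte-identically
  for (s in names(m)) expect_identical(format_danai(parse_danai(s)), s)
})

test_that("parsing captures topology, case flags and branch attachment sides", {
  p <- parse_danai("[J4]c182:c182(:c182):c182")
  expect_identical(p$topology, "J")
  expect_identical(p$order, 4L)
  expect_identical(p$backbone$species, rep("C182", 3))
  expect_false(any(p$backbone$upper))
  # "(:X)" binds backward: attaches to the species before it (position 2)
  expect_identical(p$branches$attach, 2L)

  p5 <- parse_danai("[J5]c182:(c182:)c182(:c182):c182")
  expect_identical(p5$order, 5L)
  expect_identical(nrow(p5$backbone), 3L)
  # "(X:)" binds forward: both branches sit on the middle species
  expect_identical(p5$branches$attach, c(2L, 2L))

  # forward-branch fixture with explicit side semantics
  pf <- parse_danai("[J4]c180:(c180:)c180:c180")
  expect_identical(pf$branches$attach, 2L)

  r <- parse_danai("[R3]c182:c180:c182:c182")
  expect_identical(r$topology, "R")
  expect_identical(r$backbone$species, c("C182", "C180", "C182", "C182"))

  up <- parse_danai("[L2]C182:C180")
  expect_true(all(up$backbone$upper))
  expect_identical(up$macro, "ID_180_182")
})

test_that("malformed statements raise syntax errors with an offset", {
  expect_error(parse_danai("[L3]c182:c182"), "must list 3 species")
  expect_error(parse_danai("[X3]c182:c182:c182"), "unknown topology")
  expect_error(parse_danai("[R3]c182:c180:c182:c180"), "closure")
  expect_error(parse_danai("[L2]c182:c182:"), "dangling")
  expect_error(parse_danai("[L2]c182::c182"), "colon")
  expect_error(parse_danai("[J4]c182(:c182):c182:c182"), "interior")
  expect_error(parse_danai("[J4]c182:(c182:):c182:c182"),
               "species|branch|colon")
  expect_error(parse_danai("[L2]c182 c182"), "character")
  expect_error(parse_danai("[L2]cX:c182"), "species|character")
})

test_that("all 20 built-ins are canonical; canonicalization is idempotent", {
  m <- builtin_modes()
  for (s in names(m))
    expect_identical(format_danai(canonicalize_danai(m[[s]])), s)
  # random valid patterns: canonicalize . canonicalize = canonicalize
  set.seed(77)
  rand_pattern <- function() {
    topo <- sample(c("L", "R", "J"), 1)
    sp <- function(n) sample(c("C180", "C182"), n, replace = TRUE)
    up <- function(n) sample(c(TRUE, FALSE), n, replace = TRUE)
    txt <- switch(topo,
      L = {
        n <- sample(2:3, 1)
        s <- mapply(danai:::.species_text, sp(n), up(n))
        paste0("[L", n, "]", paste(s, collapse = ":"))
      },
      R = {
        s <- mapply(danai:::.species_text, sp(3), up(3))
        paste0("[R3]", paste(c(s, s[1]), collapse = ":"))
      },
      J = {
        nb <- sample(1:2, 1)
        s <- mapply(danai:::.species_text, sp(3 + nb), up(3 + nb))
        if (nb == 1)
          paste0("[J4]", s[1], ":", s[2], "(:", s[4], "):", s[3])
        else
          paste0("[J5]", s[1], ":(", s[4], ":)", s[2], "(:", s[5], "):", s[3])
      })
    parse_danai(txt)
  }
  for (i in 1:200) {
    p <- rand_pattern()
    c1 <- canonicalize_danai(p)
    c2 <- canonicalize_danai(c1)
    expect_identical(format_danai(c2), format_danai(c1))
    # case flags survive canonicalization (distinct participants only:
    # a ring's duplicated closure row depends on where the ring is opened)
    members <- function(q) {
      rows <- if (q$topology == "R") seq_len(q$order) else seq_len(nrow(q$backbone))
      sort(paste0(c(q$backbone$species[rows], q$branches$species),
                  c(q$backbone$upper[rows], q$branches$upper)))
    }
    expect_identical(members(c1), members(p))
    # parse/format round trip on the canonical form
    expect_identical(format_danai(parse_danai(format_danai(c1))),
                     format_danai(c1))
  }
})

test_that("symmetric rewritings of one motif canonicalize identically", {
  set.seed(31)
  for (i in 1:50) {
    sp <- sample(c("c180", "c182", "C180", "C182"), 3, replace = TRUE)
    # a ring read from every rotation and both directions
    readings <- c(
      vapply(0:2, function(r) {
        s <- sp[(((0:2) + r) %% 3) + 1]
        paste0("[R3]", paste(c(s, s[1]), collapse = ":"))
      }, character(1)),
      vapply(0:2, function(r) {
        s <- rev(sp)[(((0:2) + r) %% 3) + 1]
        paste0("[R3]", paste(c(s, s[1]), collapse = ":"))
      }, character(1)))
    canon <- vapply(readings, function(s)
      format_danai(canonicalize_danai(parse_danai(s))), character(1))
    expect_length(unique(canon), 1L)
    # a linear chain and its reverse reading
    l <- sample(c("c180", "c182", "C180", "C182"), 3, replace = TRUE)
    lf <- paste0("[L3]", paste(l, collapse = ":"))
    lr <- paste0("[L3]", paste(rev(l), collapse = ":"))
    expect_identical(format_danai(canonicalize_danai(parse_danai(lf))),
                     format_danai(canonicalize_danai(parse_danai(lr))))
  }
})

test_that("published lexicographic example: reversed L3 reading", {
  p <- parse_danai("[L3]c182:c180:c180")
  expect_identical(format_danai(canonicalize_danai(p)),
                   format_danai(canonicalize_danai(
                     parse_danai("[L3]c180:c180:c182"))))
})
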