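tr_sys <- function(variant = "plus_op")
  grow_shoot(species_preset("trifolium_repens", variant = variant))

test_that("structural capacity shrinks by attachment point plus delay", {
  expect_identical(structural_length(21, 1, 2), 18L)
  expect_identical(structural_length(21, 19, 2), 0L)
  expect_identical(structural_length(18, 1, 2), 15L)
  expect_error(structural_length(21, 0, 2), ">= 1")
})

test_that("AL thresholds classify buds into the three base categories", {
  p <- species_preset("trifolium_repens")
  expect_identical(classify_al(6.5019, p), "branch")
  expect_identical(classify_al(0.5, p), "unemerged")
  expect_identical(classify_al(1.4642, p), "short_shoot")
  # inclusive comparisons
  expect_identical(classify_al(6, p), "branch")
  expect_identical(classify_al(1.3, p), "short_shoot")
  expect_error(classify_al(-1, p), "non-negative")
  # structural downgrade only demotes branch-level ALs at cramped positions
  pd <- p; pd$structural_downgrade <- TRUE
  expect_identical(classify_al(50, pd, structural = 2), "short_shoot")
  expect_identical(classify_al(50, pd, structural = 3), "branch")
})

test_that("the T. repens +OP system reproduces the published architecture", {
  sys <- tr_sys()
  primary <- sys$buds[sys$buds$order == 1L, ]
  branch_nodes <- primary$primary_node[
    primary$category %in% c("branch_unbranched", "branch_branched")]
  expect_identical(sort(branch_nodes), 1:11)

  # exactly one bud of path length 3 reaches branch level, at (1,1,1)
  deep <- sys$buds[sys$buds$order == 3L &
                   sys$buds$category %in% c("branch_unbranched",
                                            "branch_branched"), ]
  expect_identical(deep$path, "1.1.1")

  # the tertiary branch at (1,1) bears it, hence is a branched branch
  expect_identical(sys$buds$category[sys$buds$path == "1.1"],
                   "branch_branched")
})

test_that("the -OP variant over-predicts: 15 branched tertiaries", {
  sys <- tr_sys("minus_op")
  bb2 <- sys$buds[sys$buds$order == 2L &
                  sys$buds$category == "branch_branched", ]
  expect_identical(nrow(bb2), 15L)
  expect_true(all(bb2$primary_node %in% 1:5))
})

test_that("enumeration matches the first-principles oracle, both variants", {
  for (variant in c("plus_op", "minus_op")) {
    sys <- tr_sys(variant)
    oracle <- oracle_enumerate(0.78, 2, 21, 6, 1.3,
                               plus_op = variant == "plus_op")
    expect_setequal(sys$buds$path, oracle$path)
    o <- oracle[match(sys$buds$path, oracle$path), ]
    expect_equal(sys$buds$al, o$al, tolerance = 1e-9)
    base_cat <- sub("branch_.*", "branch", sys$buds$category)
    expect_identical(base_cat, o$category)
    expect_identical(sys$buds$effective_length, as.integer(o$eff))
    expect_identical(sys$buds$category == "branch_branched", o$branched)
    expect_lt(nrow(sys$buds), 5000L)
  }
})

test_that("branched-branch refinement is exhaustively consistent", {
  for (variant in c("plus_op", "minus_op")) {
    sys <- tr_sys(variant)
    b <- sys$buds
    is_branch <- b$category %in% c("branch_unbranched", "branch_branched")
    for (i in which(is_branch)) {
      kids <- b[b$parent == b$path[i], ]
      has_branch_child <- any(kids$category %in% c("branch_unbranched",
                                                   "branch_branched"))
      expect_identical(b$category[i] == "branch_branched", has_branch_child)
    }
  }
  # a tree with no deep branches has no branched branches
  flat <- grow_shoot(shoot_params(0.78, 2, 21, 60, 1.3))
  expect_false(any(flat$buds$category == "branch_branched"))
})

test_that("emerged positions under +OP are nested within -OP", {
  plus <- tr_sys("plus_op")$buds
  minus <- tr_sys("minus_op")$buds
  emerged <- function(b) b$path[b$category != "unemerged"]
  expect_true(all(emerged(plus) %in% emerged(minus)))
})

test_that("degenerate and structural edge cases build cleanly", {
  # thresholds out of reach: a single unemerged bud, no recursion
  empty <- grow_shoot(shoot_params(0.5, 2, 1, 150, 101))
  expect_identical(nrow(empty$buds), 1L)
  expect_identical(empty$buds$category, "unemerged")
  expect_identical(empty$buds$effective_length, 0L)

  # excised primary nodes carry no buds but keep their indices
  trad <- grow_shoot(species_preset("tradescantia_fluminensis"))
  primary <- trad$buds[trad$buds$order == 1L, ]
  expect_false(any(primary$primary_node %in% 1:4))
  expect_identical(min(primary$primary_node), 5L)
  # node 5 is the first to decay under the adjustment
  expect_equal(trad$buds$nrs[trad$buds$path == "5"], 0.78)

  # short-shoot parents still host enumerated children, capped at 2 nodes
  minus <- tr_sys("minus_op")$buds
  ss <- minus[minus$category == "short_shoot", ]
  expect_true(all(ss$effective_length <= 2L))
  expect_true(any(minus$parent == "14"))  # children on the short shoot at 14
})

test_that("builds are pure functions of parameters", {
  a <- tr_sys(); b <- tr_sys()
  expect_identical(a$buds, b$buds)
})
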