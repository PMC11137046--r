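# Helper: build a panel prediction object from explicit per-drug pieces.
mk_panel <- function(cells, drugs, sets, uppers, lowers = NULL,
                     points = NULL) {
  preds <- lapply(seq_along(drugs), function(j) {
    list(cell_line = cells,
         set = sets[[j]],
         lower = if (is.null(lowers)) uppers[[j]] - 0.2 else lowers[[j]],
         upper = uppers[[j]],
         point_value = if (is.null(points)) uppers[[j]] - 0.1
         else points[[j]])
  })
  names(preds) <- drugs
  drug_panel_prediction(preds)
}

test_that("effective drugs are exactly the singleton-sensitive sets", {
  cells <- "CL_1"
  panel <- mk_panel(cells, c("a", "b", "c", "d"),
                    sets = list(list("1"), list(c("0", "1")), list("0"),
                                list(character(0))),
                    uppers = list(0.3, 0.2, 0.1, 0.4))
  expect_equal(effective_drugs(panel, "CL_1"), "a")

  # all full sets (Summation-style degeneracy) -> nothing is effective
  full <- mk_panel(cells, c("a", "b"),
                   sets = list(list(c("0", "1")), list(c("0", "1"))),
                   uppers = list(0.1, 0.2))
  expect_length(effective_drugs(full, "CL_1"), 0)
  expect_error(effective_drugs(panel, "CL_9"), "not in panel")
})

test_that("ranking is ascending by upper limit with deterministic tie
           breaks", {
  cells <- "CL_1"
  panel <- mk_panel(cells, c("a", "b", "c"),
                    sets = rep(list(list("1")), 3),
                    uppers = list(0.2, 0.1, 0.4))
  r <- rank_drugs(panel, "CL_1")
  expect_equal(r$drug, c("b", "a", "c"))
  expect_equal(r$rank, 1:3)
  expect_true(all(diff(r$upper) >= 0))

  # equal uppers: point value then drug id decide
  tie <- mk_panel(cells, c("z", "y", "x"),
                  sets = rep(list(list("1")), 3),
                  uppers = list(0.3, 0.3, 0.3),
                  points = list(0.25, 0.25, 0.1))
  expect_equal(rank_drugs(tie, "CL_1")$drug, c("x", "y", "z"))

  empty <- mk_panel(cells, c("a", "b"),
                    sets = list(list("0"), list("0")),
                    uppers = list(0.1, 0.2))
  expect_equal(nrow(rank_drugs(empty, "CL_1")), 0)
})

test_that("adding drugs with non-singleton sets never changes the
           list", {
  cells <- c("CL_1", "CL_2")
  sets_a <- list(list("1"), list("1"))
  sets_b <- list(list("1"), list("0"))
  base <- mk_panel(cells, c("a", "b"), list(sets_a, sets_b),
                   uppers = list(c(0.2, 0.3), c(0.1, 0.5)))
  extra <- mk_panel(cells, c("a", "b", "noise"),
                    list(sets_a, sets_b,
                         list(c("0", "1"), character(0))),
                    uppers = list(c(0.2, 0.3), c(0.1, 0.5), c(0, 0)))
  for (cl in cells)
    expect_equal(rank_drugs(base, cl)$drug, rank_drugs(extra, cl)$drug)
})

test_that("prioritization evaluation measures precision, best-drug
           retention, rank and gap", {
  cells <- "CL_1"
  drugs <- c("a", "b", "c", "d")
  tv <- setNames(c(0.25, 0.30, 0.6, 0.9), drugs)
  tl <- setNames(c(1, 1, 1, 0), drugs)

  # oracle: list equals the true sensitive set sorted by true viability
  oracle <- mk_panel(cells, drugs,
                     sets = list(list("1"), list("1"), list("1"),
                                 list("0")),
                     uppers = as.list(tv))
  ev <- evaluate_prioritization(rank_drugs(oracle, "CL_1"), tv, tl)
  expect_equal(ev$precision, 1)
  expect_equal(ev$first_rank, 1)
  expect_equal(ev$viability_gap, 0)
  expect_true(ev$best_contained && ev$first_is_tp)

  # 4 listed, 3 truly sensitive -> precision 0.75; first drug b:
  # rank 2 in the true ordering, gap 0.30 - 0.25 = 0.05
  mixed <- mk_panel(cells, drugs,
                    sets = rep(list(list("1")), 4),
                    uppers = list(0.35, 0.1, 0.5, 0.7))
  ev2 <- evaluate_prioritization(rank_drugs(mixed, "CL_1"), tv, tl)
  expect_equal(ev2$precision, 0.75)
  expect_equal(ev2$first_rank, 2)
  expect_equal(ev2$viability_gap, 0.05, tolerance = 1e-12)
  expect_true(ev2$best_contained)

  # empty list -> undefined, not an error
  none <- mk_panel(cells, drugs, sets = rep(list(list("0")), 4),
                   uppers = as.list(tv))
  ev3 <- evaluate_prioritization(rank_drugs(none, "CL_1"), tv, tl)
  expect_false(ev3$defined)
  expect_true(is.na(ev3$precision))
})

test_that("oracle predictions prioritize every synthetic cell line
           perfectly", {
  pan <- simulate_shared_panel(n_drugs = 6, n = 80, p = 10, seed = 31)
  test_cells <- as.character(pan$split$test)
  drugs <- colnames(pan$labels)
  preds <- lapply(drugs, function(dr) {
    lab <- pan$labels[test_cells, dr]
    vb <- pan$viability[test_cells, dr]
    list(cell_line = test_cells,
         set = lapply(lab, function(l) as.character(l)),
         lower = vb, upper = vb, point_value = vb)
  })
  names(preds) <- drugs
  panel <- drug_panel_prediction(preds)
  res <- prioritize_panel(panel, pan$viability, pan$labels)
  # oracle sets + degenerate intervals at the true viabilities
  expect_equal(res$aggregate$median_precision, 1)
  expect_equal(res$aggregate$frac_first_tp, 1)
  per <- res$per_cell_line
  expect_true(all(per$precision[!is.na(per$precision)] == 1))
})

test_that("panels reject drugs with differing test cell lines", {
  preds <- list(
    a = list(cell_line = c("CL_1", "CL_2"), set = list("1", "1"),
             lower = c(0, 0), upper = c(1, 1)),
    b = list(cell_line = c("CL_1", "CL_3"), set = list("1", "1"),
             lower = c(0, 0), upper = c(1, 1)))
  expect_error(drug_panel_prediction(preds), "share the same test")
})
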