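test_that("score formulas are exact on enumerated confusion tables", {
  # tp=2 tn=2 fp=1 fn=1 -> precision 2/3, accuracy 2/3, F-score 2/3
  rows <- data.frame(
    compound_id = paste0("c", 1:6),
    assay_kind = "substrate_growth",
    experimental = c("positive", "positive", "negative", "negative",
                     "negative", "positive"),
    stringsAsFactors = FALSE)
  predicted <- data.frame(predicted = c("positive", "positive", "negative",
                                        "negative", "positive", "negative"))
  res <- score_validation(predicted, phenotype_table(rows))
  expect_equal(c(res$tp, res$tn, res$fp, res$fn), c(2, 2, 1, 1))
  expect_identical(res$precision, 2 / 3)
  expect_identical(res$accuracy, 2 / 3)
  expect_identical(res$f_score, 2 / 3)
  expect_identical(res$recall, 2 / 3)

  # all rows correct -> all scores 1
  all_right <- data.frame(predicted = rows$experimental)
  res1 <- score_validation(all_right, phenotype_table(rows))
  expect_identical(c(res1$precision, res1$recall, res1$accuracy,
                     res1$f_score), c(1, 1, 1, 1))
})

test_that("scores are invariant under row permutation", {
  pf <- make_phenotype_fixture(10, 0.3, seed = 5)
  pred <- predict_phenotypes(pf$network, pf$table, pf$medium)
  res <- score_validation(pred, pf$table)
  perm <- sample(nrow(pf$table$rows))
  tbl2 <- phenotype_table(pf$table$rows[perm, ])
  res2 <- score_validation(pred[perm, ], tbl2)
  expect_equal(res2[c("tp", "tn", "fp", "fn", "f_score", "accuracy")],
               res[c("tp", "tn", "fp", "fn", "f_score", "accuracy")])
})

test_that("flipping one correct row to incorrect never increases accuracy", {
  pf <- make_phenotype_fixture(10, 0.2, seed = 9)
  pred <- predict_phenotypes(pf$network, pf$table, pf$medium)
  base <- score_validation(pred, pf$table)$accuracy
  for (i in seq_len(nrow(pf$table$rows))) {
    p2 <- pred
    p2$predicted[i] <- if (pred$predicted[i] == "positive") "negative"
                       else "positive"
    acc <- score_validation(p2, pf$table)$accuracy
    correct_before <- pred$predicted[i] == pf$table$rows$experimental[i]
    if (correct_before) expect_lte(acc, base)
  }
})

test_that("predictions match the per-substrate LP oracle", {
  pf <- make_phenotype_fixture(12, 0, seed = 1)
  pred <- predict_phenotypes(pf$network, pf$table, pf$medium)
  # oracle: brute-force FBA per substrate row with that compound as the sole
  # carbon source; product rows by direct secretion maximization at 90%
  # of optimal growth
  for (i in seq_len(nrow(pf$table$rows))) {
    row <- pf$table$rows[i, ]
    if (row$assay_kind == "substrate_growth") {
      med <- medium(uptake_bounds = stats::setNames(10, row$compound_id),
                    carbon_source_id = row$compound_id)
      g <- fba(apply_medium(pf$network, med))$objective_value
      expect_identical(pred$predicted[i],
                       if (g > 1e-6) "positive" else "negative")
    } else {
      net <- apply_medium(pf$network, pf$medium)
      mu_star <- fba(net)$objective_value
      bi <- match(net$biomass_reaction_id, net$reactions$id)
      net$reactions$lower_bound[bi] <- 0.9 * mu_star
      v <- fba(net, objective = row$compound_id)$objective_value
      expect_identical(pred$predicted[i],
                       if (v > 1e-6) "positive" else "negative")
    }
  }
  # with error_rate 0 the table equals model behavior: perfect scores
  expect_identical(score_validation(pred, pf$table)$f_score, 1)
})

test_that("compounds without an exchange reaction are negative and flagged", {
  pf <- make_phenotype_fixture(6, 0, seed = 1)
  rows <- pf$table$rows
  rows$compound_id[1] <- "EX_not_present"
  rows$experimental[1] <- "positive"
  tbl <- phenotype_table(rows)
  pred <- predict_phenotypes(pf$network, tbl, pf$medium)
  expect_identical(pred$predicted[1], "negative")
  expect_true(pred$flagged[1])
})

test_that("misaligned predictions are rejected", {
  pf <- make_phenotype_fixture(6, 0, seed = 1)
  pred <- predict_phenotypes(pf$network, pf$table, pf$medium)
  expect_error(score_validation(pred[-1, ], pf$table), "rows")
})

test_that("phenotype CSV round trip", {
  pf <- make_phenotype_fixture(8, 0.25, seed = 4)
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pf$table$rows, p, row.names = FALSE)
  tbl <- read_phenotype_csv(p)
  expect_equal(tbl$rows$compound_id, pf$table$rows$compound_id)
  expect_equal(tbl$rows$experimental, pf$table$rows$experimental)
})
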