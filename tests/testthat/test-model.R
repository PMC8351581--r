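test_that("grid search returns the only point of a singleton grid", {
  set.seed(51)
  dat <- spiked_set(n_pos = 12, n_neg = 12, effect = 4, seed = 5)
  x <- build_feature_matrix(dat$records, descriptor_spec("GTPC"))
  gs <- grid_search_cv(x, dat$labels, algorithm = "DT",
                       grid = list(list(max_depth = 5)), seed = 1)
  expect_equal(gs$best_params, list(max_depth = 5))
  expect_equal(nrow(gs$grid_metrics), 1L)
  expect_error(grid_search_cv(x, dat$labels, "NeuralNet"), "valid")
})

test_that("strongly separable synthetic data is learned almost perfectly", {
  dat <- generate_proteins(synthetic_config(n_pos = 20, n_neg = 20,
                                            length_range = c(35, 80),
                                            effect = 8, seed = 9))
  x <- build_feature_matrix(dat$records, descriptor_spec("CTDC"))
  gs <- grid_search_cv(x, dat$labels, algorithm = "SVM", seed = 2,
                       grid = lapply(c(1, 10),
                                     function(C) list(kernel = "radial",
                                                      cost = C,
                                                      gamma = "scale")))
  expect_gte(max(gs$grid_metrics$mean_auprc), 0.95)
})

test_that("training is deterministic and survives serialization for every algorithm", {
  dat <- spiked_set(n_pos = 15, n_neg = 15, effect = 6, seed = 13)
  held <- generate_proteins(synthetic_config(n_pos = 10, n_neg = 10,
                                             length_range = c(35, 80),
                                             effect = 6, mode = "motif-spike",
                                             seed = 99))
  grids <- list(XGBoost = list(list(nrounds = 40, max_depth = 3, eta = 0.3)),
                SVM = list(list(kernel = "radial", cost = 1, gamma = "scale")),
                RF = list(list(ntree = 100, max_features = "sqrt")),
                DT = list(list(max_depth = 5)),
                KNN = list(list(k = 3)))
  tf <- withr::local_tempfile(fileext = ".rds")
  for (algo in names(grids)) {
    fit1 <- pmp_train(dat, descriptor = descriptor_spec("GTPC"),
                      algorithm = algo, grid = grids[[algo]], seed = 4)
    fit2 <- pmp_train(dat, descriptor = descriptor_spec("GTPC"),
                      algorithm = algo, grid = grids[[algo]], seed = 4)
    expect_equal(fit1$cv$scores, fit2$cv$scores, label = algo)
    p1 <- predict(fit1, held$records)
    expect_equal(p1, predict(fit2, held$records), label = algo)
    save_model(fit1, tf)
    expect_equal(predict(load_model(tf), held$records), p1, label = algo)
    expect_true(all(p1$score >= 0 & p1$score <= 1), label = algo)
  }
})

test_that("training-set AUC on a strongly separable fixture is essentially 1", {
  dat <- spiked_set(n_pos = 15, n_neg = 15, effect = 8, seed = 17)
  fit <- pmp_train(dat, descriptor = descriptor_spec("GTPC"),
                   algorithm = "XGBoost",
                   grid = list(list(nrounds = 60, max_depth = 3, eta = 0.3)),
                   seed = 6)
  pred <- predict(fit, dat$records)
  m <- compute_metrics(pred$score, dat$labels)
  expect_gte(m$auc, 0.99)
})

test_that("prediction respects batch equivariance, thresholds and per-record diagnostics", {
  dat <- spiked_set(n_pos = 12, n_neg = 12, effect = 6, seed = 21)
  fit <- pmp_train(dat, descriptor = descriptor_spec("GTPC"),
                   algorithm = "DT", grid = list(list(max_depth = 5)),
                   seed = 3)
  batch <- predict(fit, dat$records)
  single <- do.call(rbind, lapply(seq_len(nrow(dat$records)), function(i) {
    predict(fit, dat$records[i, , drop = FALSE])
  }))
  rownames(single) <- NULL
  expect_equal(batch, single)

  # a score exactly at the threshold is called moonlighting
  s1 <- batch$score[1]
  at <- predict(fit, dat$records[1, , drop = FALSE], threshold = s1)
  expect_equal(at$label, "moonlighting")

  # empty input -> empty output
  expect_equal(nrow(predict(fit, protein_records(character(0),
                                                 character(0)))), 0L)

  # a too-short record is reported without aborting the batch
  mixed <- protein_records(c("ok", "tiny"),
                           c(dat$records$sequence[1], "MK"))
  pm <- predict(fit, mixed)
  expect_equal(pm$score[1], batch$score[1])
  expect_true(is.na(pm$score[2]))
  expect_match(pm$note[2], "shorter")
  expect_true(is.na(pm$label[2]))
})

test_that("feature-class ranking is deterministic and ordered by AUPRC", {
  dat <- spiked_set(n_pos = 12, n_neg = 12, effect = 6, seed = 25)
  specs <- list(descriptor_spec("GTPC"), descriptor_spec("GTPC"),
                descriptor_spec("CTDC"))
  tab <- rank_feature_classes(dat$records, dat$labels, specs = specs,
                              seed = 8, grid = list(list(kernel = "radial",
                                                         cost = 1,
                                                         gamma = "scale")))
  expect_equal(nrow(tab), 3L)
  # identical specs give identical metrics under the same seed
  g <- tab[tab$class == "GTPC", ]
  expect_equal(g$auprc[1], g$auprc[2])
  expect_equal(g$auc[1], g$auc[2])
  expect_true(all(diff(tab$auprc) <= 1e-12))
})
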