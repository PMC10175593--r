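# one small shared panel keeps this file fast
small_panel <- generate_panel(sim_config(n_per_class = 6, p_nir = 50,
                                         nir_peak_sd = 350, seed = 17))
small_cars <- cars_config(N = 20, folds = 5, max_lv = 4, seed = 3)

test_that("selection covers only the included blocks and honors thresholds", {
  ds <- assemble_dataset(small_panel$dataset$blocks[c("EN", "ET")],
                         small_panel$dataset$labels, "authenticity")
  cfg <- pipeline_config("authenticity", blocks = c("EN", "ET"), seed = 1,
                         max_lv = 4)
  sel <- select_features(ds, cfg)
  expect_setequal(names(sel), c("EN", "ET"))
  expect_true(all(vapply(sel, function(s) length(s$indices) > 0, logical(1))))
  # threshold 0 selects everything
  cfg0 <- pipeline_config("authenticity", blocks = c("EN", "ET"),
                          vip_threshold = 0, seed = 1, max_lv = 4)
  sel0 <- select_features(ds, cfg0)
  expect_equal(length(sel0$EN$indices), 10L)
  expect_equal(length(sel0$ET$indices), 6L)
})

test_that("fusing concatenates selected columns with faithful provenance", {
  ds <- small_panel$dataset
  sel <- structure(list(
    EN = list(indices = c(2L, 5L), names = ds$blocks$EN$var_names[c(2, 5)],
              method = "VIP"),
    ET = list(indices = 3L, names = ds$blocks$ET$var_names[3],
              method = "lambda")), class = "selection_result")
  fused <- fuse_blocks(ds, sel)
  expect_equal(ncol(fused$values), 3L)
  expect_equal(nrow(fused$provenance), 3L)
  expect_false(anyDuplicated(fused$provenance$fused_name) > 0)
  # every fused column maps back to its block column
  for (r in seq_len(nrow(fused$provenance))) {
    src <- fused$provenance$block[r]
    v <- fused$provenance$variable[r]
    expect_equal(unname(fused$values[, r]),
                 unname(ds$blocks[[src]]$values[, v]))
  }
  # single block: fusion is the identity on the selected columns
  one <- fuse_blocks(ds, structure(sel["EN"], class = "selection_result"))
  expect_equal(unname(one$values),
               unname(ds$blocks$EN$values[, c(2, 5)]))
})

test_that("the pipeline is deterministic and composes from its modules", {
  ds <- assemble_dataset(small_panel$dataset$blocks[c("EN", "ET")],
                         small_panel$dataset$labels, "species")
  cfg <- pipeline_config("species", blocks = c("EN", "ET"), seed = 5,
                         max_pc = 5)
  r1 <- run_pipeline(ds, cfg)
  r2 <- run_pipeline(ds, cfg)
  expect_equal(r1$metrics$accuracy, r2$metrics$accuracy)
  expect_identical(r1$selection$EN$indices, r2$selection$EN$indices)
  expect_identical(as.character(r1$cv$pred), as.character(r2$cv$pred))

  # single-block run equals calling the modules directly
  cfg_en <- pipeline_config("species", blocks = "EN", seed = 5, max_pc = 5)
  ds_en <- assemble_dataset(small_panel$dataset$blocks["EN"],
                            small_panel$dataset$labels, "species")
  rp <- run_pipeline(ds_en, cfg_en)
  cls <- dataset_classes(ds_en)
  st <- stepwise_eliminate(ds_en$blocks$EN$values, cls, max_pc = 5)
  x_sel <- ds_en$blocks$EN$values[, st$selected, drop = FALSE]
  expect_identical(unname(rp$selection$EN$indices), unname(st$selected))
  cv <- loocv(x_sel, cls, list(method = "pcada", n_pc = rp$hyper$n_pc,
                               max_pc = 5, pretreatment = "autoscale"))
  expect_identical(as.character(rp$cv$pred), as.character(cv$pred))
})

test_that("authenticity reports carry ROC, VIP explanation and t-tests", {
  ds <- assemble_dataset(small_panel$dataset$blocks[c("EN", "EE")],
                         small_panel$dataset$labels, "authenticity")
  cfg <- pipeline_config("authenticity", blocks = c("EN", "EE"), seed = 2,
                         max_lv = 4)
  r <- run_pipeline(ds, cfg)
  expect_s3_class(r, "fusion_report")
  expect_true(!is.null(r$roc))
  expect_gte(r$roc$auc, 0)
  expect_true(all(c("vip", "high_contribution", "t_p_value") %in%
                    colnames(r$explanation)))
  expect_equal(nrow(r$explanation), ncol(r$fused))
  expect_equal(sum(r$confusion), nrow(ds$labels))
})

test_that("species reports flag low-lambda fused variables", {
  ds <- assemble_dataset(small_panel$dataset$blocks[c("EN", "ET")],
                         small_panel$dataset$labels, "species")
  r <- run_pipeline(ds, pipeline_config("species", blocks = c("EN", "ET"),
                                        seed = 3, max_pc = 5))
  expect_true(all(c("lambda", "high_contribution") %in% colnames(r$explanation)))
  expect_equal(r$explanation$high_contribution, r$explanation$lambda < 0.3)
})

test_that("any block subset runs without error, including NIR via CARS", {
  ds4 <- small_panel$dataset
  cfg <- pipeline_config("species", blocks = c("EE", "NIR"), seed = 4,
                         max_pc = 5, cars = small_cars)
  r <- run_pipeline(assemble_dataset(ds4$blocks[c("EE", "NIR")], ds4$labels,
                                     "species"), cfg)
  expect_s3_class(r$selection$NIR$criterion, "cars_trace")
  expect_gte(r$metrics$accuracy, 0)
})

test_that("nested LOOCV refits selection per fold and still reports sane metrics", {
  tiny <- generate_panel(sim_config(n_per_class = 5, p_nir = 30,
                                    nir_peak_sd = 500, seed = 23))
  ds <- assemble_dataset(tiny$dataset$blocks["EN"], tiny$dataset$labels,
                         "authenticity")
  cfg <- pipeline_config("authenticity", blocks = "EN", seed = 6, max_lv = 3,
                         nested = TRUE)
  r <- run_pipeline(ds, cfg)
  expect_length(r$cv$pred, 20L)
  expect_gte(r$metrics$accuracy, 0)
  expect_lte(r$metrics$accuracy, 1)
})
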