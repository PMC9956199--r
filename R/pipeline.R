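#' Full-pipeline configuration
#'
#' One config object driving the end-to-end workflow: synthesize a cohort,
#' encrypt it into a ciphertext store, decrypt, split 80/20, select CCRBM
#' initial parameters by whale optimization, train, predict and evaluate.
#' Every stochastic stage derives its own seed deterministically from the
#' master seed, so stages can be enabled or disabled without perturbing one
#' another.
#'
#' @param synthetic A [synthetic_config()]; default 2000 records, 5
#'   features, effect size 2.
#' @param structure A [ccrbm_structure()].
#' @param scheme Encryption scheme for the store; default `"paillier"`.
#' @param key_bits Key size in bits; default 512.
#' @param precision Fixed-point digits; default 6.
#' @param learning_rate CD learning rate; default 0.1.
#' @param train_fraction Train share of the outer split; default 0.8.
#' @param validation_fraction Share of the training split held out as the
#'   optimizer's validation set; default 0.2.
#' @param woa_population,woa_iterations Whale population (default 20) and
#'   iteration budget (default 100).
#' @param woa_bounds Symmetric search box half-width for every parameter
#'   dimension; default 1 (the box \[-1, 1\]).
#' @param inner_epochs CD epochs inside each fitness evaluation; default 5.
#' @param final_epochs CD epochs of the final training run; default 50.
#' @param cd_k Gibbs steps per CD update; default 1.
#' @param fitness `"accuracy"` (negative validation accuracy, default) or
#'   `"reconstruction"` (validation reconstruction error).
#' @param encrypt Route the cohort through the encrypted store (default
#'   `TRUE`); `FALSE` bypasses encryption, which must not change the
#'   learned model.
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, structure = ccrbm_structure(),
                            scheme = c("paillier", "rsa"), key_bits = 512L,
                            precision = 6L, learning_rate = 0.1,
                            train_fraction = 0.8, validation_fraction = 0.2,
                            woa_population = 20L, woa_iterations = 100L,
                            woa_bounds = 1, inner_epochs = 5L,
                            final_epochs = 50L, cd_k = 1L,
                            fitness = c("accuracy", "reconstruction"),
                            encrypt = TRUE, seed = 1L) {
  scheme <- match.arg(scheme)
  fitness <- match.arg(fitness)
  if (is.null(synthetic))
    synthetic <- synthetic_config(2000L, seed = derive_seed(seed, "synth"))
  if (synthetic$n_features != structure$visible_length)
    stopf("cohort has %d features but the CCRBM expects %d",
          synthetic$n_features, structure$visible_length)
  structure(list(synthetic = synthetic, structure = structure,
                 scheme = scheme, key_bits = as.integer(key_bits),
                 precision = as.integer(precision),
                 learning_rate = learning_rate,
                 train_fraction = train_fraction,
                 validation_fraction = validation_fraction,
                 woa_population = as.integer(woa_population),
                 woa_iterations = as.integer(woa_iterations),
                 woa_bounds = woa_bounds,
                 inner_epochs = as.integer(inner_epochs),
                 final_epochs = as.integer(final_epochs),
                 cd_k = as.integer(cd_k), fitness = fitness,
                 encrypt = isTRUE(encrypt), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Unflatten a whale position into CCRBM parameters
#'
#' The position vector lays out the filters row-major, then the hidden
#' biases, then the visible bias — `n_filters * filter_width + n_filters +
#' 1` dimensions in total. Centering offsets are initialised to the sigmoid
#' of the corresponding biases, as at any fresh parameter initialisation.
#' `params_to_whale` is the exact inverse on the encoded fields.
#'
#' @param position Numeric vector of the documented length.
#' @param structure A [ccrbm_structure()].
#' @param learning_rate Learning rate carried on the parameters.
#' @return A [ccrbm_params()].
#' @export
whale_to_params <- function(position, structure, learning_rate = 0.1) {
  l <- structure$n_filters; w <- structure$filter_width
  want <- l * w + l + 1L
  if (length(position) != want)
    stopf("position has length %d, expected %d (= %d*%d + %d + 1)",
          length(position), want, l, w, l)
  ccrbm_params(structure,
               filters = matrix(position[seq_len(l * w)], l, w, byrow = TRUE),
               beta = position[l * w + seq_len(l)],
               o = position[l * w + l + 1L],
               learning_rate = learning_rate)
}

#' @rdname whale_to_params
#' @param params A [ccrbm_params()].
#' @export
params_to_whale <- function(params) {
  c(as.vector(t(params$filters)), params$beta, params$o)
}

#' Fitness of a candidate initial-parameter vector
#'
#' Unflattens the position, trains the CCRBM for a short budget
#' (`inner_epochs` of centered CD) on the inner training split, fits the
#' readout, and scores the inner validation split. With the default
#' `"accuracy"` objective the returned fitness is the negative validation
#' accuracy (bounded in \[-1, 0\]); `"reconstruction"` returns the
#' validation reconstruction error. Deterministic given position and seed;
#' a training failure returns the worst fitness with a warning so the
#' optimizer continues.
#'
#' @param position Whale position vector.
#' @param train,validation Cohort `data.frame`s.
#' @param config A [pipeline_config()].
#' @return Scalar fitness (minimised).
#' @export
ccrbm_fitness <- function(position, train, validation, config) {
  fit_seed <- derive_seed(config$seed, "fitness")
  res <- tryCatch({
    params <- whale_to_params(position, config$structure,
                              config$learning_rate)
    model <- ccrbm_fit(train, params = params,
                       epochs = config$inner_epochs, cd_k = config$cd_k,
                       seed = fit_seed)
    if (config$fitness == "accuracy") {
      pred <- predict(model, validation)
      -mean(pred$label == validation$label)
    } else {
      reconstruction_error(cohort_features(validation), model$params)
    }
  }, error = function(e) {
    warnf("fitness evaluation failed (%s); returning worst fitness",
          conditionMessage(e))
    if (config$fitness == "accuracy") 0 else Inf
  })
  res
}

#' Train a CCRBM with whale-optimised initial parameters
#'
#' Splits the training records into inner train/validation sets, runs whale
#' optimization over the flattened initial-parameter box, then trains the
#' final model from the best position for `final_epochs` of centered CD on
#' the full training set.
#'
#' @param train Training cohort.
#' @param config A [pipeline_config()].
#' @param optimize Set `FALSE` for the random-initialisation ablation: skip
#'   the optimizer and train from a random draw inside the same box.
#' @return A list with the trained `model` (class `ccrbm_model`) and the
#'   optimizer `history` (`NULL` for the ablation).
#' @export
run_ccrbm_wo <- function(train, config, optimize = TRUE) {
  validate_cohort(train)
  inner <- split_cohort(train, 1 - config$validation_fraction,
                        seed = derive_seed(config$seed, "inner-split"))
  dim <- config$structure$n_filters * config$structure$filter_width +
    config$structure$n_filters + 1L
  history <- NULL
  if (optimize) {
    wcfg <- woa_config(dim, lower = -config$woa_bounds,
                       upper = config$woa_bounds,
                       population_size = config$woa_population,
                       iterations = config$woa_iterations,
                       seed = derive_seed(config$seed, "woa"))
    opt <- woa_optimize(function(pos)
      ccrbm_fitness(pos, inner$train, inner$test, config), wcfg)
    start <- opt$best_position
    history <- opt$history
  } else {
    start <- with_seed(derive_seed(config$seed, "random-init"),
                       runif(dim, -config$woa_bounds, config$woa_bounds))
  }
  params <- whale_to_params(start, config$structure, config$learning_rate)
  model <- ccrbm_fit(train, params = params, epochs = config$final_epochs,
                     cd_k = config$cd_k,
                     seed = derive_seed(config$seed, "final-train"))
  list(model = model, history = history)
}

#' Run the full privacy-preserving detection pipeline
#'
#' Synthesize the cohort, generate keys, encrypt into a ciphertext store,
#' decrypt, split 80/20 (stratified), train the whale-optimised CCRBM,
#' predict on the held-out records and evaluate. The encryption layer is
#' lossless at the configured fixed-point precision, so disabling it
#' (`encrypt = FALSE` in the config) yields the identical model. With
#' `output_dir` given, all artifacts (cohort CSV, key JSONs, ciphertext
#' store, model JSON, optimizer history, evaluation report) are written,
#' each stamped with the master seed and a config hash.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for the run artifacts.
#' @param dictionary Optional numeric dictionary handed to the simulated
#'   adversary of [security_analysis()]; defaults to the fixed-point grid
#'   values 0, 0.5 and 1 plus every distinct feature value of up to 50
#'   records (a strong, covering adversary at small scale).
#' @return A list with `cohort`, `split`, `model`, `woa_history`,
#'   `predictions`, `report` (an `evaluation_report`), `timings_ms`, and
#'   `artifacts` (paths, when `output_dir` was given).
#' @export
run_full_pipeline <- function(config, output_dir = NULL, dictionary = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "synthesize"
  result <- tryCatch({
    cohort <- generate_cohort(config$synthetic)

    stage <- "keygen"
    key <- NULL
    bt_ms <- 0
    if (config$encrypt) {
      key <- he_keygen(config$scheme, config$key_bits,
                       seed = derive_seed(config$seed, "keys"))
      bt_ms <- key$bt_ms
    }

    stage <- "encrypt"
    store <- with_seed(derive_seed(config$seed, "encrypt"),
                       encrypt_cohort(cohort, key, config$precision))

    stage <- "decrypt"
    decrypted <- decrypt_cohort(store, key)
    if (!isTRUE(all.equal(cohort_features(decrypted),
                          cohort_features(cohort),
                          tolerance = 10^(-config$precision))))
      stopf("decrypted features deviate from the originals beyond 1e-%d",
            config$precision)

    stage <- "split"
    split <- split_cohort(decrypted, config$train_fraction,
                          seed = derive_seed(config$seed, "split"))

    stage <- "train"
    trained <- run_ccrbm_wo(split$train, config)

    stage <- "predict"
    predictions <- predict(trained$model, split$test)

    stage <- "evaluate"
    counts <- confusion_counts(split$test$label, predictions$label)
    metrics <- compute_metrics(counts)
    timings <- c(at_ms = store$meta$at_ms, bt_ms = bt_ms,
                 ct_ms = attr(decrypted, "ct_ms"))
    if (is.null(dictionary)) {
      head_feats <- cohort_features(cohort)[seq_len(min(50, nrow(cohort))), ]
      dictionary <- unique(c(0, 0.5, 1, as.vector(head_feats)))
    }
    security <- security_analysis(store, key, dictionary,
                                  seed = derive_seed(config$seed,
                                                     "adversary"))
    report <- evaluation_report(metrics, timings, security)

    artifacts <- NULL
    if (!is.null(output_dir)) {
      stage <- "persist"
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      pth <- function(f) file.path(output_dir, f)
      artifacts <- list(cohort = pth("cohort.csv"),
                        public_key = pth("key_public.json"),
                        private_key = pth("key_private.json"),
                        store = pth("store.json"),
                        model = pth("model.json"),
                        woa_history = pth("woa_history.jsonl"),
                        report = pth("report.json"))
      write_cohort(cohort, artifacts$cohort)
      if (config$encrypt)
        write_keys(key, artifacts$public_key, artifacts$private_key)
      write_store(store, artifacts$store)
      write_model(trained$model, artifacts$model)
      if (!is.null(trained$history)) {
        con <- file(artifacts$woa_history, "w")
        for (i in seq_len(nrow(trained$history)))
          writeLines(jsonlite::toJSON(as.list(trained$history[i, ]),
                                      auto_unbox = TRUE, digits = NA), con)
        close(con)
      }
      stamp <- list(seed = config$seed,
                    config_hash = substr(sha256_hex(paste(
                      deparse(unclass(config)), collapse = "")), 1, 16))
      rep_doc <- c(unclass(report), list(provenance = stamp))
      jsonlite::write_json(rep_doc, artifacts$report, auto_unbox = TRUE,
                           digits = NA, null = "null")
    }
    list(cohort = cohort, split = split, model = trained$model,
         woa_history = trained$history, predictions = predictions,
         report = report, timings_ms = timings, artifacts = artifacts)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  result
}
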