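# Orchestration of the two study designs: (1) a small head-to-head where a
# Hill model is CMA-ES-fitted and networks are trained on the same single
# trial, then both are evaluated on four scenarios (same/other bird x
# same/other muscle); (2) a leave-one-bird-out study where networks are
# trained on the training muscle of all but one bird and tested on held-out
# trials, the excluded bird, and the other muscle.

predict_trial_force <- function(model, trial, f_max) {
  d <- trial$data
  if (inherits(model, "nn_model")) {
    stats::predict(model, d$activation, d$lce, d$vce) * f_max
  } else if (inherits(model, "hill_params")) {
    hill_force(d$activation, d$lce, d$vce, model, f_max)
  } else stop("unsupported model type")
}

# Evaluate one or more models (pooled over models and trials) on a set of
# trials; returns a metrics_report. f_max comes from each trial's meta.
evaluate_on_trials <- function(models, trials) {
  if (!is.list(models) || inherits(models, c("nn_model", "hill_params"))) {
    models <- list(models)
  }
  measured <- list(); estimated <- list(); fmaxes <- c(); fss <- c()
  for (mod in models) {
    for (tr in trials) {
      measured <- c(measured, list(tr$data$force))
      estimated <- c(estimated, list(predict_trial_force(mod, tr, tr$meta$f_max)))
      fmaxes <- c(fmaxes, tr$meta$f_max)
      fss <- c(fss, tr$meta$fs)
    }
  }
  if (length(measured) == 0) return(NULL)
  build_report(measured, estimated, fmaxes, fss)
}

scenario_trials <- function(dataset, train_bird, train_muscle,
                            exclude_ids = character(0)) {
  meta <- trial_meta(dataset)
  muscles <- unique(meta$muscle)
  other_muscles <- setdiff(muscles, train_muscle)
  not_train <- function(trs) {
    trs[!vapply(trs, function(tr) tr$meta$trial_id %in% exclude_ids, logical(1))]
  }
  birds <- unique(meta$bird_id)
  other_birds <- setdiff(birds, train_bird)
  list(
    same_bird_same_muscle = not_train(
      filter_trials(dataset, bird_id = train_bird, muscle = train_muscle)),
    same_bird_other_muscle = filter_trials(dataset, bird_id = train_bird,
                                           muscle = other_muscles),
    other_bird_same_muscle = filter_trials(dataset, bird_id = other_birds,
                                           muscle = train_muscle),
    other_bird_other_muscle = filter_trials(dataset, bird_id = other_birds,
                                            muscle = other_muscles)
  )
}

#' Head-to-head comparison of a network and a Hill fit on one trial
#'
#' Fits the Hill model by CMA-ES and trains network repeats on the same
#' single trial, then evaluates both on the four test scenarios: remaining
#' trials of the training bird and muscle, the other muscle of the same
#' bird, the same muscle of other birds, and the other muscle of other
#' birds.
#'
#' @param dataset a `trial_dataset`.
#' @param train_bird,train_muscle training selection.
#' @param train_trial_id `trial_id` of the training trial (default: the
#'   first trial of that bird and muscle).
#' @param nn_cfg an [nn_config()] (default 10 repeats, as used for
#'   single-trial training).
#' @param hill_iter CMA-ES generations.
#' @param seed master seed (fans out to fit and training seeds).
#' @param arch optional fixed network architecture (skips the search).
#' @return list: `hill_fit`, `nn_models`, `reports` (per scenario, each a
#'   list with `hill` and `nn` metrics_report), `comparison` (tidy
#'   data.frame), `train_trial_id`.
#' @export
run_head_to_head <- function(dataset, train_bird = 1, train_muscle = "LG",
                             train_trial_id = NULL,
                             nn_cfg = nn_config(n_repeats = 10),
                             hill_iter = 100, seed = 1L, arch = NULL) {
  train_pool <- filter_trials(dataset, bird_id = train_bird,
                              muscle = train_muscle)
  if (length(train_pool) == 0) stop("no trials match the training selection")
  if (is.null(train_trial_id)) train_trial_id <- train_pool[[1]]$meta$trial_id
  train_trial <- Filter(function(tr) tr$meta$trial_id == train_trial_id,
                        train_pool)
  if (length(train_trial) != 1) stop("training trial not found: ", train_trial_id)
  train_trial <- train_trial[[1]]
  seeds <- derive_seeds(seed, 2)

  hf <- fit_cmaes(train_trial, f_max = train_trial$meta$f_max,
                  n_iter = hill_iter, seed = seeds[1])
  nn_cfg$seed <- seeds[2]
  nns <- search_and_train(train_trial, nn_cfg, arch = arch)

  scen <- scenario_trials(dataset, train_bird, train_muscle,
                          exclude_ids = train_trial_id)
  reports <- lapply(scen, function(trs) {
    if (length(trs) == 0) return(NULL)
    list(hill = evaluate_on_trials(hf$params, trs),
         nn = evaluate_on_trials(nns, trs))
  })
  comparison <- do.call(rbind, lapply(names(reports), function(nm) {
    rep <- reports[[nm]]
    if (is.null(rep)) return(NULL)
    do.call(rbind, lapply(c("hill", "nn"), function(model) {
      a <- rep[[model]]$aggregate
      data.frame(scenario = nm, model = model,
                 force_mrmse = a$force_mrmse, r2_median = a$r2_median,
                 missed_pct = a$missed_pct_mean, extra_pct = a$extra_pct_mean,
                 rise_mrmse = a$rise_mrmse, fall_mrmse = a$fall_mrmse)
    }))
  }))
  list(hill_fit = hf, nn_models = nns, reports = reports,
       comparison = comparison, train_trial_id = train_trial_id,
       seed = seed)
}

#' Leave-one-bird-out network training and evaluation
#'
#' Trains network repeats on the training muscle (default LG) of every bird
#' except `excluded_bird`, holding out one trial per training bird (the
#' last one). Tests on: the held-out trials of the training birds, all
#' training-muscle trials of the excluded bird, and all other-muscle
#' trials. Asserts that no trial appears in both training and test
#' manifests.
#'
#' @param dataset a `trial_dataset`.
#' @param excluded_bird bird id left out of training.
#' @param train_muscle training muscle id.
#' @param nn_cfg an [nn_config()] (default 5 repeats, as used for large
#'   datasets).
#' @param seed master seed.
#' @param arch optional fixed architecture.
#' @return list: `nn_models`, `reports` (metrics_report per bird-muscle
#'   subgroup), `table` (tidy data.frame), `train_ids`, `test_ids`.
#' @export
run_leave_one_out <- function(dataset, excluded_bird, train_muscle = "LG",
                              nn_cfg = nn_config(n_repeats = 5), seed = 1L,
                              arch = NULL) {
  meta <- trial_meta(dataset)
  birds <- unique(meta$bird_id)
  train_birds <- setdiff(birds, excluded_bird)
  if (length(train_birds) < 1) stop("need at least 2 birds for leave-one-out")
  train_trials <- list(); heldout <- list()
  for (b in train_birds) {
    trs <- filter_trials(dataset, bird_id = b, muscle = train_muscle)
    if (length(trs) == 0) next
    if (length(trs) > 1) {
      train_trials <- c(train_trials, trs[-length(trs)])
      heldout <- c(heldout, trs[length(trs)])
    } else {
      train_trials <- c(train_trials, trs)
    }
  }
  if (length(train_trials) == 0) stop("no training trials available")
  train_ids <- vapply(train_trials, function(tr) tr$meta$trial_id, character(1))

  nn_cfg$seed <- derive_seeds(seed, 1)
  nns <- search_and_train(train_trials, nn_cfg, arch = arch)

  other_muscles <- setdiff(unique(meta$muscle), train_muscle)
  test_sets <- list()
  for (tr in heldout) {
    key <- sprintf("bird%s_%s", tr$meta$bird_id, tr$meta$muscle)
    test_sets[[key]] <- c(test_sets[[key]], list(tr))
  }
  excl <- filter_trials(dataset, bird_id = excluded_bird, muscle = train_muscle)
  if (length(excl)) {
    test_sets[[sprintf("bird%s_%s", excluded_bird, train_muscle)]] <- excl
  }
  for (m in other_muscles) {
    for (b in birds) {
      trs <- filter_trials(dataset, bird_id = b, muscle = m)
      if (length(trs)) test_sets[[sprintf("bird%s_%s", b, m)]] <- trs
    }
  }
  test_ids <- unlist(lapply(test_sets, function(trs) {
    vapply(trs, function(tr) tr$meta$trial_id, character(1))
  }))
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap)) {
    stop("training/test manifests overlap: ", paste(overlap, collapse = ", "))
  }

  reports <- lapply(test_sets, function(trs) evaluate_on_trials(nns, trs))
  tbl <- do.call(rbind, lapply(names(reports), function(nm) {
    a <- reports[[nm]]$aggregate
    data.frame(subgroup = nm, force_mrmse = a$force_mrmse,
               rrmse_pct = a$rrmse_pct_mean,
               r2_median = a$r2_median, r2_min = a$r2_min, r2_max = a$r2_max,
               missed_pct = a$missed_pct_mean, extra_pct = a$extra_pct_mean,
               rise_mrmse = a$rise_mrmse, fall_mrmse = a$fall_mrmse)
  }))
  list(nn_models = nns, reports = reports, table = tbl,
       train_ids = train_ids, test_ids = unname(test_ids), seed = seed)
}
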