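# Dataset files are long-format CSV (header row, UTF-8, "." decimal):
#   ratings.csv  subject, item_id, rating
#   trials.csv   subject, trial_id, step, item_id, is_catch
#   choices.csv  subject, trial_id, chosen_item, confidence
# Numeric columns are written with 17 significant digits so that a write /
# read cycle reproduces the in-memory doubles exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write likeability ratings to CSV
#' @param subjects list of subjects (each with \code{items}), or a single
#'   subject list.
#' @param path output file.
#' @export
write_ratings_csv <- function(subjects, path) {
  subjects <- as_subject_list(subjects)
  d <- do.call(rbind, lapply(seq_along(subjects), function(i)
    data.frame(subject = i, item_id = subjects[[i]]$items$item_id,
               rating = fmt_num(subjects[[i]]$items$rating))))
  write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write trial sequences to CSV (one row per sampling step)
#' @inheritParams write_ratings_csv
#' @export
write_trials_csv <- function(subjects, path) {
  subjects <- as_subject_list(subjects)
  d <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]$session
    do.call(rbind, lapply(seq_along(s$sequences), function(t)
      data.frame(subject = i, trial_id = t,
                 step = seq_along(s$sequences[[t]]),
                 item_id = s$sequences[[t]], is_catch = s$is_catch[t])))
  }))
  write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write choices to CSV
#' @inheritParams write_ratings_csv
#' @export
write_choices_csv <- function(subjects, path) {
  subjects <- as_subject_list(subjects)
  d <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    ch <- subjects[[i]]$choices
    data.frame(subject = i, trial_id = ch$trial_id, chosen_item = ch$chosen,
               confidence = fmt_num(ch$confidence))
  }))
  write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

as_subject_list <- function(x) {
  if (!is.null(x$items)) list(x) else x
}

io_error <- function(file, msg, ...) {
  stop_invalid(paste0("%s: ", msg), file, ...)
}

#' Read a dataset (ratings, trial sequences, optional choices)
#'
#' Reads the long-format CSV files written by the \code{write_*_csv}
#' functions (or prepared externally to the same schema) and
#' cross-validates them: ratings within 0-100, every trial item rated,
#' every chosen item a member of its trial's sequence, no choices for
#' unknown trials. A write/read cycle reproduces the in-memory structures
#' exactly.
#'
#' @param ratings_path,trials_path,choices_path file paths;
#'   \code{choices_path} may be NULL.
#' @param profile profile label to attach to the reconstructed sessions.
#' @return list of subjects, each with \code{items}, \code{session} and
#'   (if available) \code{choices}.
#' @export
read_choice_data <- function(ratings_path, trials_path, choices_path = NULL,
                             profile = "custom") {
  rt <- read.csv(ratings_path, fileEncoding = "UTF-8")
  need <- c("subject", "item_id", "rating")
  if (!all(need %in% names(rt)))
    io_error(ratings_path, "missing column(s) %s",
             paste(setdiff(need, names(rt)), collapse = ", "))
  bad <- which(rt$rating < 0 | rt$rating > 100 | !is.finite(rt$rating))
  if (length(bad))
    io_error(ratings_path, "rating outside [0,100] at data row(s) %s",
             paste(head(bad, 5L), collapse = ", "))
  tr <- read.csv(trials_path, fileEncoding = "UTF-8")
  need <- c("subject", "trial_id", "step", "item_id", "is_catch")
  if (!all(need %in% names(tr)))
    io_error(trials_path, "missing column(s) %s",
             paste(setdiff(need, names(tr)), collapse = ", "))
  ch <- if (!is.null(choices_path)) {
    x <- read.csv(choices_path, fileEncoding = "UTF-8")
    need <- c("subject", "trial_id", "chosen_item")
    if (!all(need %in% names(x)))
      io_error(choices_path, "missing column(s) %s",
               paste(setdiff(need, names(x)), collapse = ", "))
    x
  }
  lapply(sort(unique(rt$subject)), function(s) {
    items <- rt[rt$subject == s, ]
    out_items <- data.frame(item_id = items$item_id, rating = items$rating,
                            category = "file")
    class(out_items) <- c("cc_items", "data.frame")
    strials <- tr[tr$subject == s, ]
    ids <- sort(unique(strials$trial_id))
    seqs <- lapply(ids, function(t) {
      rows <- strials[strials$trial_id == t, ]
      unknown <- setdiff(rows$item_id, out_items$item_id)
      if (length(unknown))
        io_error(trials_path, "subject %s trial %s: unrated item(s) %s",
                 s, t, paste(unknown, collapse = ", "))
      as.integer(rows$item_id[order(rows$step)])
    })
    is_catch <- vapply(ids, function(t)
      as.logical(strials$is_catch[strials$trial_id == t][1L]), TRUE)
    session <- new_session(seqs, is_catch, profile, NA_integer_)
    sub <- list(items = out_items, session = session)
    if (!is.null(ch)) {
      sch <- ch[ch$subject == s, ]
      unknown <- setdiff(sch$trial_id, ids)
      if (length(unknown))
        io_error(choices_path, "subject %s: choices for unknown trial(s) %s",
                 s, paste(unknown, collapse = ", "))
      for (k in seq_len(nrow(sch))) {
        t <- match(sch$trial_id[k], ids)
        if (!sch$chosen_item[k] %in% seqs[[t]])
          io_error(choices_path,
                   "subject %s trial %s: chosen item %s not in sequence",
                   s, sch$trial_id[k], sch$chosen_item[k])
      }
      bp <- best_positions(session, out_items)
      tid <- match(sch$trial_id, ids)
      choices <- data.frame(
        trial_id = as.integer(sch$trial_id),
        length = bp$length[tid], is_catch = is_catch[tid],
        chosen = as.integer(sch$chosen_item),
        chosen_pos = vapply(seq_len(nrow(sch)), function(k)
          match(sch$chosen_item[k], seqs[[tid[k]]]), 0L),
        confidence = if ("confidence" %in% names(sch))
          sch$confidence else NA_real_,
        best = bp$best[tid], best_pos = bp$best_pos[tid],
        chose_best = as.integer(sch$chosen_item) == bp$best[tid],
        p_best = NA_real_)
      class(choices) <- c("cc_choices", "data.frame")
      sub$choices <- choices
    }
    sub
  })
}

# ---- pipeline ----------------------------------------------------------

#' Read a pipeline configuration file (YAML or JSON)
#' @param path configuration file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes design + simulation, model fitting, Bayesian model selection,
#' model recovery and the model-free analyses as requested by the
#' configuration, writing all tables, the echoed configuration and a
#' report (JSON and plain text) into the output directory. Every
#' stochastic stage is driven by the global \code{seed}, so a rerun with
#' the same configuration reproduces the report exactly.
#'
#' Configuration fields: \code{seed}; \code{profile}; \code{n_subjects};
#' \code{skew}; \code{model} (generating model name) with optional
#' \code{params} (named list); optional \code{fit} (list with
#' \code{models}, \code{n_starts}); flags \code{bms} and \code{analyze};
#' optional \code{recover} (list with \code{models},
#' \code{generate_from}, \code{n_groups}, \code{n_starts}).
#'
#' @param config configuration list or path to a YAML/JSON file.
#' @param out_dir output directory (created if missing); defaults to
#'   \code{config$out}.
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out %||% stop_invalid("no output directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  model <- config$model %||% "H2.1"
  if (!model %in% model_names())
    stop_invalid("unknown model name '%s' in config", model)
  if (!is.null(config$fit$models)) {
    unknown <- setdiff(config$fit$models, model_names())
    if (length(unknown))
      stop_invalid("unknown model name(s) in config: %s",
                   paste(unknown, collapse = ", "))
  }
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report <- list(seed = seed, model = model,
                 package_version = as.character(utils::packageVersion("covertchoice")))

  spec <- model_spec(model)
  params <- do.call(model_params, as.list(config$params %||% list()))
  subjects <- run_stage("simulate", simulate_group(
    spec, params, n_subjects = config$n_subjects %||% 30L,
    profile = config$profile %||% "exp1", seed = seed,
    skew = config$skew %||% 0.3))
  write_ratings_csv(subjects, file.path(out_dir, "ratings.csv"))
  write_trials_csv(subjects, file.path(out_dir, "trials.csv"))
  write_choices_csv(subjects, file.path(out_dir, "choices.csv"))
  report$n_subjects <- length(subjects)

  if (isTRUE(config$analyze) || is.null(config$analyze)) {
    mf <- run_stage("analyze", modelfree_report(subjects))
    write.csv(mf, file.path(out_dir, "modelfree.csv"), row.names = FALSE)
    pb <- run_stage("analyze", pbest_by_position(subjects))
    write.csv(pb$cells, file.path(out_dir, "pbest_by_position.csv"),
              row.names = FALSE)
    report$modelfree <- mf
  }

  if (!is.null(config$fit)) {
    fg <- run_stage("fit", {
      set.seed(seed)
      fit_group(subjects, config$fit$models,
                n_starts = config$fit$n_starts %||% 5L)
    })
    ev <- data.frame(subject = rep(seq_len(nrow(fg$evidence)),
                                   ncol(fg$evidence)),
                     model = rep(colnames(fg$evidence),
                                 each = nrow(fg$evidence)),
                     free_energy = as.vector(fg$evidence))
    write.csv(ev, file.path(out_dir, "evidence.csv"), row.names = FALSE)
    report$evidence_models <- colnames(fg$evidence)
    report$fit_settings <- list(
      n_starts = config$fit$n_starts %||% 5L,
      priors = lapply(setNames(nm = config$fit$models),
                      function(m) default_priors(model_spec(m))))
    if (isTRUE(config$bms)) {
      b <- run_stage("bms", bms(fg$evidence, seed = seed))
      jsonlite::write_json(list(models = b$models, alpha = b$alpha,
                                ef = b$ef, ep = b$ep),
                           file.path(out_dir, "bms.json"), digits = NA)
      report$bms <- list(models = b$models, ef = b$ef, ep = b$ep)
    }
  }

  if (!is.null(config$recover)) {
    rc <- run_stage("recover", model_recovery(
      models = config$recover$models %||% c("H0", "H1", "H2", "H2.1", "H3"),
      generate_from = config$recover$generate_from %||% config$recover$models,
      n_groups = config$recover$n_groups %||% 10L,
      n_subjects = config$n_subjects %||% 30L,
      profile = config$profile %||% "exp1", seed = seed,
      n_starts = config$recover$n_starts %||% 5L))
    write.csv(rc$confusion, file.path(out_dir, "recovery.csv"))
    report$recovery <- rc$confusion
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       matrix = "columnmajor")
  txt <- utils::capture.output(utils::str(report, give.attr = FALSE))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}
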