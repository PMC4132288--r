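## Config-driven end-to-end run: generator (or session files) ->
## classification tables, population statistics, difference maps,
## selectivity table, behavior table, run manifest.

#' Analysis configuration
#'
#' Thresholds and windows used by [run_pipeline()], with the standard
#' defaults: Bonferroni screen alpha 0.05/4 = 0.0125, 200-ms map windows,
#' map alpha 0.05, 10 map trials, 3-SD outlier exclusion.
#'
#' @param screen_alpha Per-odor screen threshold.
#' @param map_window Sliding-window length, seconds.
#' @param map_alpha Per-cell map threshold.
#' @param map_trials Trial axis length for maps.
#' @param outlier_k SD multiplier for selectivity outlier exclusion.
#' @param welltime_window Behavioral well-time window, seconds.
#' @param n_subjects Number of probe-day subjects simulated for the
#'   behavioral ANOVA.
#' @param epochs Epoch overrides ([default_epochs()]).
#' @return List of class `ub_analysis_config`.
#' @export
analysis_config <- function(screen_alpha = 0.0125, map_window = 0.2,
                            map_alpha = 0.05, map_trials = 10L,
                            outlier_k = 3, welltime_window = 5,
                            n_subjects = 4L, epochs = default_epochs()) {
  stopifnot(screen_alpha > 0, screen_alpha < 1, map_alpha > 0,
            map_alpha < 1, map_window > 0)
  structure(list(screen_alpha = screen_alpha, map_window = map_window,
                 map_alpha = map_alpha, map_trials = as.integer(map_trials),
                 outlier_k = outlier_k, welltime_window = welltime_window,
                 n_subjects = as.integer(n_subjects), epochs = epochs),
            class = "ub_analysis_config")
}

.write_tab <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) learning-day and probe sessions, screens and
#' classifies units, computes population statistics (sign tests, the
#' odor-by-half repeated-measures ANOVA, flavor/number count comparison),
#' difference and significance maps for the three standard contrasts,
#' selectivity regressions, and behavioral tables, writing each artifact
#' as delimited text plus a JSON run manifest. The run is deterministic
#' given the seed. On a stage failure, partial outputs are preserved next
#' to a `FAILED` marker naming the stage.
#'
#' @param gen_config A [unblocking_config()] used to simulate sessions;
#'   ignored when `sessions` is supplied.
#' @param out_dir Output directory (created if needed).
#' @param config An [analysis_config()].
#' @param sessions Optional named list with elements `day1`, `day2`
#'   (learning `ub_session`s) and `probe` (list of probe sessions);
#'   bypasses the generator.
#' @param seed Seed for the whole run; defaults to `gen_config$seed`.
#' @param figures Also render heat-map PDFs.
#' @return Object of class `ub_pipeline`: list of artifact paths and the
#'   in-memory results, invisibly.
#' @export
run_pipeline <- function(gen_config = unblocking_config(), out_dir,
                         config = analysis_config(), sessions = NULL,
                         seed = gen_config$seed, figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  unlink(file.path(out_dir, "FAILED"))
  tryCatch({
    artifacts <- character()
    log <- character()
    note <- function(...) log <<- c(log, paste0(...))

    stage <- "generate"
    if (is.null(sessions)) {
      gen_config$seed <- as.integer(seed)
      d1 <- generate_session(gen_config, day = "1")
      d2 <- generate_session(gen_config, day = "2")
      probe_cfgs <- lapply(seq_len(config$n_subjects), function(i) {
        ci <- gen_config
        ci$seed <- as.integer((seed + 131L * i) %% .Machine$integer.max)
        ci
      })
      probes <- lapply(probe_cfgs, function(ci)
        generate_session(ci, day = "probe",
                         session_id = sprintf("sim%d_probe_s%d", seed,
                                              ci$seed))$session)
      sessions <- list(day1 = d1$session, day2 = d2$session, probe = probes)
      truth <- d1$truth
      artifacts["ground_truth"] <-
        .write_tab(truth, file.path(out_dir, "ground_truth.csv"))
      for (nm in c("day1", "day2")) {
        ep <- file.path(out_dir, paste0("session_", nm, "_events.csv"))
        sp <- file.path(out_dir, paste0("session_", nm, "_spikes.csv"))
        write_session(sessions[[nm]], ep, sp)
        artifacts[paste0(nm, "_events")] <- ep
        artifacts[paste0(nm, "_spikes")] <- sp
      }
      note("generated day1/day2 sessions with ", nrow(truth), " units; ",
           length(probes), " probe subjects")
    } else truth <- NULL

    stage <- "screen"
    scr1 <- screen_units(sessions$day1, alpha = config$screen_alpha,
                         epochs = config$epochs)
    scr2 <- screen_units(sessions$day2, alpha = config$screen_alpha,
                         epochs = config$epochs)
    pooled <- rbind(as.data.frame(scr1), as.data.frame(scr2))
    artifacts["classification"] <-
      .write_tab(pooled, file.path(out_dir, "classification.csv"))
    pc <- population_counts(c(scr1$category, scr2$category))
    counts_df <- data.frame(category = names(pc$counts),
                            count = as.integer(pc$counts),
                            fraction = as.numeric(pc$fractions))
    artifacts["counts"] <-
      .write_tab(counts_df, file.path(out_dir, "population_counts.csv"))
    note("screened ", pc$n_screened, " unit-days; odor-responsive ",
         pc$odor_responsive)

    stage <- "population_stats"
    stats_rows <- list()
    sal_ids <- scr1$unit_id[scr1$category %in% "salience"]
    pred_ids <- scr1$unit_id[grepl("^predictive", scr1$category)]
    ep <- config$epochs
    norm_rate <- function(uid, tt) {
      sp <- sessions$day1$units[[uid]]
      trs <- trials_of_type(sessions$day1, tt)
      mean(normalized_firing(epoch_rates(sp, trs, ep$odor),
                             epoch_rates(sp, trs, ep$iti)), na.rm = TRUE)
    }
    if (length(sal_ids) >= 1) {
      novel <- vapply(sal_ids, function(u)
        mean(c(norm_rate(u, "blocked"), norm_rate(u, "number"),
               norm_rate(u, "flavor"))), numeric(1))
      init <- vapply(sal_ids, function(u) norm_rate(u, "initial"),
                     numeric(1))
      st <- sign_test(novel - init)
      stats_rows$sal_sign <- data.frame(
        test = "sign_test_novel_vs_initial", population = "salience",
        statistic = st$Z, stat_name = "Z", df = NA, p = st$p,
        n = st$n, stringsAsFactors = FALSE)
    }
    if (length(pred_ids) >= 1) {
      predf <- vapply(pred_ids, function(u)
        mean(c(norm_rate(u, "number"), norm_rate(u, "flavor"))), numeric(1))
      blk <- vapply(pred_ids, function(u) norm_rate(u, "blocked"),
                    numeric(1))
      st <- sign_test(predf - blk)
      stats_rows$pred_sign <- data.frame(
        test = "sign_test_predictive_vs_blocked", population = "predictive",
        statistic = st$Z, stat_name = "Z", df = NA, p = st$p, n = st$n,
        stringsAsFactors = FALSE)
    }
    # odor x half ANOVA over the novel-odor period for each major class
    halves_frame <- function(ids) {
      do.call(rbind, lapply(ids, function(uid) {
        sp <- sessions$day1$units[[uid]]
        do.call(rbind, lapply(TRIAL_TYPES, function(tt) {
          trs <- trials_of_type(sessions$day1, tt)
          iti <- epoch_rates(sp, trs, ep$iti)
          h <- function(off) {
            r <- vapply(trs, function(tr) {
              a <- .novel_anchor(tr)
              .count_in(sp, a + off, a + off + 0.5) / 0.5
            }, numeric(1))
            mean(r - iti, na.rm = TRUE)
          }
          data.frame(unit = uid, odor = tt,
                     half = c("first", "second"),
                     value = c(h(0), h(0.5)), stringsAsFactors = FALSE)
        }))
      }))
    }
    for (cls in list(c("salience", "sal"), c("predictive", "pred"))) {
      ids <- if (cls[1] == "salience") sal_ids else pred_ids
      if (length(ids) >= 2) {
        an <- rm_anova(halves_frame(ids), factors = c("half", "odor"))
        stats_rows[[paste0(cls[2], "_anova")]] <- data.frame(
          test = paste0("halves_anova_", an$test), population = cls[1],
          statistic = an$statistic, stat_name = "F",
          df = paste0(an$df1, ",", an$df2), p = an$p,
          n = length(ids), stringsAsFactors = FALSE)
      }
    }
    nf <- c(sum(pooled$sig_flavor, na.rm = TRUE),
            sum(pooled$sig_number, na.rm = TRUE))
    if (sum(nf) > 0) {
      ct <- count_comparison(nf[1], nf[2])
      stats_rows$count <- data.frame(
        test = "count_flavor_vs_number", population = "predictive",
        statistic = ct$chisq, stat_name = "chisq", df = 1, p = ct$p,
        n = sum(nf), stringsAsFactors = FALSE)
    }
    stats_df <- do.call(rbind, stats_rows)
    artifacts["statistics"] <-
      .write_tab(stats_df, file.path(out_dir, "statistics.csv"))

    stage <- "maps"
    map_pops <- list(
      novel_vs_initial = sal_ids,
      number_vs_blocked = scr1$unit_id[scr1$sig_number %in% TRUE &
                                         grepl("^predictive",
                                               scr1$category)],
      flavor_vs_blocked = scr1$unit_id[scr1$sig_flavor %in% TRUE &
                                         grepl("^predictive",
                                               scr1$category)])
    maps <- list()
    for (ctr in names(map_pops)) {
      ids <- map_pops[[ctr]]
      if (length(ids) < 3) {
        note("map ", ctr, ": only ", length(ids), " units; skipped")
        next
      }
      m <- difference_map(sessions$day1, contrast = ctr,
                          n_trials = config$map_trials,
                          window = config$map_window,
                          alpha = config$map_alpha, units = ids,
                          epochs = ep)
      maps[[ctr]] <- m
      artifacts[paste0("map_", ctr)] <-
        .write_tab(as.data.frame(m$value),
                   file.path(out_dir, paste0("map_", ctr, "_value.csv")))
      artifacts[paste0("map_", ctr, "_p")] <-
        .write_tab(as.data.frame(m$p),
                   file.path(out_dir, paste0("map_", ctr, "_p.csv")))
      note("map ", ctr, ": ", m$n_units, " units, ",
           sum(m$degenerate), " degenerate cells")
      if (figures) {
        fp <- file.path(out_dir, paste0("map_", ctr, ".pdf"))
        grDevices::pdf(fp, width = 7, height = 4)
        plot(m); plot(m, which = "sig")
        grDevices::dev.off()
        artifacts[paste0("map_", ctr, "_fig")] <- fp
      }
    }

    stage <- "selectivity"
    sel <- selectivity_analysis(scr1, sessions$day1, k = config$outlier_k,
                                epochs = ep)
    artifacts["selectivity"] <-
      .write_tab(sel$indices, file.path(out_dir, "selectivity.csv"))
    artifacts["selectivity_regressions"] <-
      .write_tab(sel$regressions,
                 file.path(out_dir, "selectivity_regressions.csv"))

    stage <- "behavior"
    beh <- do.call(rbind, lapply(c(sessions["day1"], sessions["day2"],
                                   sessions$probe), function(s)
      cbind(session = s$session_id, day = s$day,
            session_behavior(s, config$welltime_window))))
    artifacts["behavior"] <-
      .write_tab(beh, file.path(out_dir, "behavior.csv"))
    probe_stats <- NULL
    if (length(sessions$probe) >= 2) {
      rec <- probe_records(sessions$probe, config$welltime_window)
      probe_stats <- probe_anova(rec)
      artifacts["probe_anova"] <-
        .write_tab(probe_stats$anova, file.path(out_dir, "probe_anova.csv"))
      artifacts["probe_planned"] <-
        .write_tab(probe_stats$planned,
                   file.path(out_dir, "probe_planned.csv"))
    }

    stage <- "manifest"
    manifest <- list(
      package = "unblockr",
      version = as.character(utils::packageVersion("unblockr")),
      seed = seed,
      generator = gen_config[setdiff(names(gen_config), "epochs")],
      analysis = config[setdiff(names(config), "epochs")],
      artifacts = as.list(artifacts),
      log = log)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    artifacts["manifest"] <- file.path(out_dir, "manifest.json")
    writeLines(log, file.path(out_dir, "run_log.txt"))

    invisible(structure(list(artifacts = artifacts, screen_day1 = scr1,
                             screen_day2 = scr2, counts = pc,
                             statistics = stats_df, maps = maps,
                             selectivity = sel, probe = probe_stats,
                             out_dir = out_dir, log = log),
                        class = "ub_pipeline"))
  }, error = on_fail)
}

#' @export
print.ub_pipeline <- function(x, ...) {
  cat("<ub_pipeline> ", length(x$artifacts), " artifacts in ", x$out_dir,
      "\n", sep = "")
  cat(paste0("  - ", names(x$artifacts)), sep = "\n")
  invisible(x)
}
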