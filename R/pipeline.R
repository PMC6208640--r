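.default_config <- function() {
  list(
    out_dir = ".",
    stages = c("simulate", "train", "evaluate"),
    seed = 1L,
    label = list(mode = "sign", cutoff = 2, positive_class = NULL, tol = 1e-9),
    forest = list(ntree = 500L, mtry = NULL, min_node = 1L),
    contributions = list(mode = "oob", denominator = "counted"),
    simulate = list(scenario = "single_competition", n_organisms = 20L,
                    n_metabolites = 50L, group_size = 4L, supply = 10,
                    vmax = 10, dt = 0.1, n_steps = 240L, biomass0 = 0.01),
    inputs = list(traits = NULL, interactions = NULL, model = NULL),
    explain = list(pair = NULL, candidates = "competition"),
    learning_curve = list(fractions = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6,
                                        0.7, 0.8, 0.9, 0.95),
                          n_repeats = 10L)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.log_stage <- function(stage, msg) {
  message(sprintf("%s | stage=%s | %s",
                  format(Sys.time(), "%H:%M:%S"), stage, msg))
}

.stage_fail <- function(stage, e) {
  stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the coculture-prediction pipeline
#'
#' Wires the package stages together: \code{simulate} (toy community +
#' pairwise dFBA campaign), \code{train} (composite dataset + forest),
#' \code{evaluate} (OOB metrics, ROC, permutation importance),
#' \code{baseline_jaccard}, \code{explain} (feature contributions for one
#' pair), \code{rank_mechanisms} (net-contribution rankings for every
#' sample) and \code{learning_curve}. Every run writes its resolved
#' configuration and a checksummed artifact manifest beside the outputs; all
#' randomness derives from the single seed.
#'
#' @param config configuration list or path to a YAML file; missing entries
#'   take package defaults (see the pipeline vignette).
#' @return invisibly, a list with \code{status} (0 on success) and
#'   \code{manifest} (data.frame file/md5).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_config(), config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(...) file.path(out_dir, ...)
  emit <- function(path) written <<- c(written, path)

  known <- c("simulate", "train", "evaluate", "baseline_jaccard", "explain",
             "rank_mechanisms", "learning_curve")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")", call. = FALSE)
  }

  rule <- label_rule(mode = cfg$label$mode, cutoff = cfg$label$cutoff,
                     positive_class = cfg$label$positive_class,
                     tol = cfg$label$tol)
  traits <- NULL
  tab <- NULL
  dataset <- NULL
  model <- NULL
  mechanisms <- NULL

  load_data <- function(stage) {
    if (is.null(traits)) {
      pt <- cfg$inputs$traits
      pi <- cfg$inputs$interactions
      if (is.null(pt)) pt <- put("traits.tsv")
      if (is.null(pi)) pi <- put("interactions.tsv")
      if (!file.exists(pt) || !file.exists(pi)) {
        stop(sprintf("stage '%s' failed: missing inputs %s / %s", stage, pt, pi),
             call. = FALSE)
      }
      mode <- if (rule$mode == "cutoff") "fold_change" else "relative_yield"
      traits <<- read_trait_matrix(pt)
      tab <<- read_interaction_table(pi, response_mode = mode)
      dataset <<- assemble_dataset(traits, tab, rule)
    }
  }

  for (stage in cfg$stages) {
    tryCatch({
      if (stage == "simulate") {
        sc <- cfg$simulate
        .log_stage(stage, sprintf("scenario=%s n=%d seed=%d", sc$scenario,
                                  sc$n_organisms, cfg$seed))
        gen <- generate_community(n_organisms = sc$n_organisms,
                                  n_metabolites = sc$n_metabolites,
                                  scenario = sc$scenario, seed = cfg$seed,
                                  group_size = sc$group_size,
                                  supply = sc$supply, vmax = sc$vmax,
                                  dt = sc$dt, n_steps = sc$n_steps,
                                  biomass0 = sc$biomass0)
        camp <- pairwise_campaign(gen$models, gen$env)
        traits <- traits_from_models(gen$models, gen$metabolites)
        mechanisms <- camp$mechanisms
        emit(write_trait_matrix(traits, put("traits.tsv")))
        emit(write_interaction_table(camp$table, put("interactions.tsv")))
        utils::write.table(camp$mechanisms, put("mechanisms.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit(put("mechanisms.tsv"))
        yaml::write_yaml(list(scenario = sc, seed = cfg$seed,
                              amounts = as.list(gen$env$amounts),
                              dt = gen$env$dt, n_steps = gen$env$n_steps,
                              vmax = gen$env$vmax,
                              biomass0 = gen$env$biomass0),
                         put("env.yaml"))
        emit(put("env.yaml"))
        # interactions.tsv from a simulation already holds relative yields
        tab <- camp$table
        dataset <- assemble_dataset(traits, tab, rule)
      } else if (stage == "train") {
        load_data(stage)
        .log_stage(stage, sprintf("%d samples, ntree=%d", nrow(dataset$design),
                                  cfg$forest$ntree))
        model <- train_forest(dataset, ntree = cfg$forest$ntree,
                              mtry = cfg$forest$mtry,
                              min_node = cfg$forest$min_node, seed = cfg$seed)
        emit(forest_to_json(model, put("model.json")))
        emit(write_pair_manifest(dataset, put("pairs.tsv")))
      } else if (stage == "evaluate") {
        load_data(stage)
        if (is.null(model)) {
          pm <- cfg$inputs$model
          if (is.null(pm)) pm <- put("model.json")
          model <- forest_from_json(pm)
        }
        ov <- oob_votes(model, dataset)
        keep <- !is.na(ov$fraction)
        ba <- balanced_accuracy_score(dataset$labels[keep], ov$predicted[keep],
                                      model$class_names[["positive"]])
        roc <- roc_auc(ov, dataset$labels)
        imp <- permutation_importance(model, dataset, seed = cfg$seed)
        .log_stage(stage, sprintf("oob balanced accuracy=%.4f auc=%.4f", ba,
                                  roc$auc))
        utils::write.table(
          data.frame(metric = c("oob_balanced_accuracy", "oob_auc",
                                "n_samples", "n_uncounted"),
                     value = c(ba, roc$auc, nrow(dataset$design), sum(!keep))),
          put("metrics.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        emit(put("metrics.tsv"))
        utils::write.table(roc$curve, put("roc.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit(put("roc.tsv"))
        utils::write.table(
          data.frame(feature = names(imp),
                     mean_decrease_accuracy = unname(imp)),
          put("importance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        emit(put("importance.tsv"))
      } else if (stage == "baseline_jaccard") {
        load_data(stage)
        jd <- jaccard_baseline_scores(traits, dataset)
        roc <- score_threshold_roc(jd, dataset$labels,
                                   positive = dataset$positive_class)
        .log_stage(stage, sprintf("jaccard auc=%.4f", roc$auc))
        utils::write.table(cbind(roc$curve, auc = roc$auc),
                           put("jaccard_roc.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        emit(put("jaccard_roc.tsv"))
      } else if (stage %in% c("explain", "rank_mechanisms")) {
        load_data(stage)
        if (is.null(model)) {
          pm <- cfg$inputs$model
          if (is.null(pm)) pm <- put("model.json")
          model <- forest_from_json(pm)
        }
        mets <- sub("^upt_", "", grep("^upt_", colnames(traits), value = TRUE))
        cmap <- if (identical(cfg$explain$candidates, "facilitation")) {
          candidate_map_facilitation(mets)
        } else if (identical(cfg$explain$candidates, "competition")) {
          candidate_map_competition(mets)
        } else {
          utils::read.delim(cfg$explain$candidates, stringsAsFactors = FALSE)
        }
        dmap <- stats::setNames(c("from_negative_end", "from_positive_end"),
                                unname(model$class_names))
        keys <- rownames(dataset$design)
        sel <- if (stage == "explain") {
          pr <- cfg$explain$pair
          if (is.null(pr)) stop("explain stage needs explain$pair = 'i,j'")
          if (length(pr) == 1L) pr <- strsplit(pr, ",")[[1L]]
          k <- match(paste(pr[1L], pr[2L], sep = ":"), keys)
          if (is.na(k)) stop("pair not in dataset: ", paste(pr, collapse = ","))
          k
        } else {
          seq_along(keys)
        }
        rows <- lapply(sel, function(k) {
          contrib <- feature_contributions(model, dataset$design[k, ],
                                           sample_id = k,
                                           mode = cfg$contributions$mode,
                                           denominator = cfg$contributions$denominator)
          cls <- as.character(dataset$labels[k])
          rk <- net_contributions(contrib, cmap, direction = dmap[[cls]])
          cbind(responder = dataset$pairs$responder[k],
                partner = dataset$pairs$partner[k], class = cls,
                baseline = contrib$baseline, rk)
        })
        outf <- if (stage == "explain") "contributions.tsv" else "rankings.tsv"
        utils::write.table(do.call(rbind, rows), put(outf), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit(put(outf))
        if (stage == "explain") {
          k <- sel[[1L]]
          contrib <- feature_contributions(model, dataset$design[k, ],
                                           sample_id = k,
                                           mode = cfg$contributions$mode)
          utils::write.table(
            data.frame(feature = names(contrib$phi), phi = unname(contrib$phi),
                       baseline = contrib$baseline),
            put("phi.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
          emit(put("phi.tsv"))
        }
        .log_stage(stage, sprintf("%d sample(s) ranked", length(sel)))
      } else if (stage == "learning_curve") {
        load_data(stage)
        lc <- learning_curve(dataset, fractions = cfg$learning_curve$fractions,
                             n_repeats = cfg$learning_curve$n_repeats,
                             ntree = cfg$forest$ntree, mtry = cfg$forest$mtry,
                             seed = cfg$seed)
        res <- merge(lc$results, lc$medians, by = "fraction")
        res$is_median <- res$balanced_accuracy == res$median
        utils::write.table(res[, c("fraction", "repeat_id",
                                   "balanced_accuracy", "median", "is_median")],
                           put("curve.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        emit(put("curve.tsv"))
        .log_stage(stage, sprintf("%d fractions x %d repeats",
                                  length(cfg$learning_curve$fractions),
                                  cfg$learning_curve$n_repeats))
      }
    }, error = function(e) {
      if (grepl("^stage '", conditionMessage(e))) stop(e)
      .stage_fail(stage, e)
    })
  }

  yaml::write_yaml(cfg, put("config_resolved.yaml"))
  emit(put("config_resolved.yaml"))
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, put("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(status = 0L, manifest = manifest))
}
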