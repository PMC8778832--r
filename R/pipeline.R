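# Study-shaped pipeline: dedup -> per-sequence metrics -> pooled
# RSCU/classification -> ENC/PR2/neutrality/PCA/CAI/correlations -> TSV
# tables + manifest, and a human-readable report over a completed run.

#' Build a pipeline run configuration
#'
#' Collects every knob of [run_pipeline()] into one object that is serialized
#' into the output directory, so any run can be reproduced from its
#' artifacts. Sequences come either from FASTA files (named by group) or an
#' in-memory `cds_set`; group labels always come from the configuration, not
#' from sequence headers.
#'
#' @param fasta named character vector of FASTA paths; names are group
#'   labels. Ignored when `sequences` is given.
#' @param sequences optional `cds_set` used directly.
#' @param reference optional `ref_usage`, or path to a reference table file.
#' @param reference_units units tag for a reference file path.
#' @param outliers outlier rule for the neutrality fit
#'   (`"tukey"`/`"sd3"`/`"none"`).
#' @param over,under RSCU classification thresholds.
#' @param alpha significance level for the CAI group comparison.
#' @param gc3 `"all"` (default) or `"synonymous"`: which GC3 variant feeds
#'   the neutrality regression.
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory (created if needed).
#' @return object of class `run_config`.
#' @export
run_config <- function(fasta = NULL, sequences = NULL, reference = NULL,
                       reference_units = "count",
                       outliers = c("tukey", "sd3", "none"),
                       over = 1.6, under = 0.6, alpha = 0.05,
                       gc3 = c("all", "synonymous"), seed = 1L,
                       out_dir = tempfile("cub_run_")) {
  structure(list(fasta = fasta, sequences = sequences,
                 reference = reference, reference_units = reference_units,
                 outliers = match.arg(outliers), over = over, under = under,
                 alpha = alpha, gc3 = match.arg(gc3),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full codon-usage analysis pipeline
#'
#' Deduplicates the input, computes per-sequence metrics, pooled RSCU and
#' codon classification per group, PR2 coordinates, neutrality fits with the
#' selection/mutation contribution split, Spearman correlation matrices, PCA
#' of RSCU vectors and (when a reference is supplied) CAI with a pairwise
#' group comparison; writes every table as TSV into the output directory
#' together with the serialized configuration and a manifest with file
#' checksums. Any stage failure aborts with the stage name.
#'
#' @param config a `run_config`.
#' @return object of class `cub_run`: list with `dir`, `files` (paths),
#'   `metrics`, `fits`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- .stage("input", {
    s <- if (!is.null(config$sequences)) config$sequences
    else if (!is.null(config$fasta)) {
      stopifnot(!is.null(names(config$fasta)))
      structure(unlist(lapply(names(config$fasta), function(g) {
        unclass(read_fasta(config$fasta[[g]], group = g))
      }), recursive = FALSE), class = "cds_set")
    } else stop("no input sequences")
    if (length(s) == 0) stop("no input sequences")
    s
  })
  ref <- .stage("reference", {
    r <- config$reference
    if (is.character(r)) r <- read_reference_table(r, config$reference_units)
    r
  })
  seqs <- .stage("deduplicate", deduplicate(seqs))
  groups <- vapply(seqs, `[[`, "", "group")
  scopes <- c(list(overall = seq_along(seqs)),
              split(seq_along(seqs), groups))
  files <- character()
  put <- function(name, df) {
    p <- .write_tsv(df, file.path(config$out_dir, name))
    files[[name]] <<- p
  }

  metrics <- .stage("metrics", codon_metrics(seqs, ref = ref))
  put("metrics.tsv", cbind(metrics[, c("id", "group")],
                           round(metrics[, -(1:2)], 6)))

  .stage("composition", {
    qty <- c("A", "C", "U", "G", "A3s", "C3s", "U3s", "G3s",
             "GC", "GC1", "GC2", "GC3", "GC12", "GC3s")
    comp <- data.frame(quantity = qty)
    for (sc in names(scopes)) {
      m <- metrics[scopes[[sc]], qty, drop = FALSE]
      comp[[sc]] <- sprintf("%.2f ± %.2f", colMeans(m),
                            apply(m, 2, stats::sd))
      comp[[paste0(sc, "_mean")]] <- round(colMeans(m), 6)
    }
    put("composition.tsv", comp)
  })

  pooled <- .stage("rscu", {
    pooled <- lapply(scopes, function(idx)
      rscu_profile(pool_counts(seqs[idx])))
    tab <- data.frame(codon = pooled[[1]]$codon, aa = pooled[[1]]$aa)
    for (sc in names(pooled)) tab[[sc]] <- round(pooled[[sc]]$rscu, 4)
    put("rscu_pooled.tsv", tab)
    m <- rscu_matrix(seqs)
    put("rscu_by_sequence.tsv",
        data.frame(id = rownames(m), group = groups, round(m, 4),
                   check.names = FALSE))
    pooled
  })

  .stage("classification", {
    rows <- lapply(names(pooled), function(sc) {
      cl <- classify_rscu(pooled[[sc]], reference = ref,
                          over = config$over, under = config$under)
      data.frame(scope = sc,
                 preferred = paste(cl$preferred, collapse = " "),
                 over_represented = paste(cl$over_represented, collapse = " "),
                 under_represented = paste(cl$under_represented, collapse = " "),
                 shared_with_reference = if (is.null(ref)) NA_character_
                 else paste(shared_preferred(cl, classify_rscu(
                   setNames(ref$rscu, ref$codon))), collapse = " "))
    })
    put("classification.tsv", do.call(rbind, rows))
  })

  put("pr2_points.tsv", .stage("pr2", {
    pr <- pr2_points(seqs)
    pr[, c("at_bias", "gc_bias")] <- round(pr[, c("at_bias", "gc_bias")], 6)
    pr
  }))

  fits <- .stage("neutrality", {
    gc3col <- if (config$gc3 == "all") "GC3" else "GC3s"
    fits <- list()
    rows <- lapply(names(scopes), function(sc) {
      idx <- scopes[[sc]]
      x <- metrics[[gc3col]][idx]
      y <- metrics$GC12[idx]
      if (length(idx) < 3 || stats::sd(x) == 0) {
        if (sc == "overall") stop("overall neutrality fit infeasible")
        return(data.frame(scope = sc, n_used = NA, n_removed = NA,
                          slope = NA, intercept = NA, pearson_r = NA,
                          pearson_p = NA, spearman_rho = NA, spearman_p = NA,
                          selection_pct = NA, mutation_pct = NA,
                          note = "skipped: too few points or constant GC3"))
      }
      f <- suppressWarnings(
        neutrality_fit(y, x, outliers = config$outliers))
      fits[[sc]] <<- f
      data.frame(scope = sc, n_used = f$n_used, n_removed = f$n_removed,
                 slope = round(f$slope, 6), intercept = round(f$intercept, 6),
                 pearson_r = round(f$pearson$r, 6),
                 pearson_p = signif(f$pearson$p, 6),
                 spearman_rho = round(f$spearman$rho, 6),
                 spearman_p = signif(f$spearman$p, 6),
                 selection_pct = round(f$contribution[["selection"]], 2),
                 mutation_pct = round(f$contribution[["mutation"]], 2),
                 note = "")
    })
    put("neutrality_fit.tsv", do.call(rbind, rows))
    fits
  })

  .stage("correlation", {
    for (sc in names(scopes)) {
      idx <- scopes[[sc]]
      if (length(idx) < 5) next
      cm <- spearman_matrix(metrics[idx, , drop = FALSE])
      tab <- data.frame(variable = rownames(cm$rho),
                        matrix(paste0(round(cm$rho, 2),
                                      ifelse(cm$stars == "", "",
                                             paste0(" ", cm$stars))),
                               nrow(cm$rho),
                               dimnames = list(NULL, colnames(cm$rho))),
                        check.names = FALSE)
      put(paste0("correlation_", sc, ".tsv"), tab)
    }
  })

  .stage("pca", {
    if (length(seqs) >= 3) {
      m <- rscu_matrix(seqs)
      k <- min(2L, nrow(m) - 1L)
      pc <- pca_rscu(m, k = k)
      put("pca_scores.tsv",
          data.frame(id = rownames(pc$scores), group = groups,
                     round(pc$scores, 6), check.names = FALSE))
      put("pca_variance.tsv",
          data.frame(component = paste0("PC", seq_along(pc$var_explained)),
                     var_explained_pct = round(100 * pc$var_explained, 2)))
      put("pca_loadings.tsv",
          data.frame(codon = rownames(pc$loadings), round(pc$loadings, 6),
                     check.names = FALSE))
    }
  })

  .stage("cai_groups", {
    if (!is.null(ref)) {
      sizes <- table(groups)
      ok <- names(sizes)[sizes >= 3]
      if (length(ok) >= 2) {
        sel <- groups %in% ok
        cmpn <- cai_group_comparison(metrics$CAI[sel], groups[sel],
                                     alpha = config$alpha)
        put("cai_groups.tsv",
            data.frame(group = names(cmpn$means),
                       mean_cai = round(as.numeric(cmpn$means), 4),
                       letter = cmpn$letters[names(cmpn$means)]))
        pm <- as.data.frame(round(cmpn$p, 6))
        put("cai_pairwise_p.tsv", cbind(group = rownames(cmpn$p), pm))
      }
    }
  })

  .stage("manifest", {
    cfg <- config
    cfg$sequences <- if (is.null(config$sequences)) NULL
      else sprintf("<in-memory cds_set of %d sequences>",
                   length(config$sequences))
    cfg$reference <- if (is.null(ref)) NULL
      else if (is.character(config$reference)) config$reference
      else "<in-memory ref_usage>"
    yaml::write_yaml(unclass(cfg), file.path(config$out_dir, "config.yaml"))
    manifest <- list(
      package = "codonusage",
      version = as.character(utils::packageVersion("codonusage")),
      seed = config$seed,
      n_sequences = length(seqs),
      groups = as.list(table(groups)),
      config_md5 = unname(tools::md5sum(file.path(config$out_dir,
                                                  "config.yaml"))),
      files = as.list(vapply(files, function(p)
        unname(tools::md5sum(p)), "")))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  structure(list(dir = config$out_dir, files = files, metrics = metrics,
                 fits = fits),
            class = "cub_run")
}

#' @export
print.cub_run <- function(x, ...) {
  cat("<cub_run> ", length(x$files), " tables in ", x$dir, "\n", sep = "")
  cat(" ", paste(names(x$files), collapse = ", "), "\n")
  invisible(x)
}

#' Write a human-readable summary of a completed pipeline run
#'
#' Assembles a markdown summary citing every table the run produced: group
#' sizes, composition highlights, classification counts, the neutrality
#' contribution sentence, PCA variance and the CAI letter display. File
#' checksums are verified against the manifest; a mismatch adds an integrity
#' warning to the report (and raises an R warning).
#'
#' @param dir a completed run directory (or a `cub_run`).
#' @param path output file (default `report.md` inside the run directory).
#' @return the report path, invisibly.
#' @export
write_report <- function(dir, path = NULL) {
  if (inherits(dir, "cub_run")) dir <- dir$dir
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path)
  if (is.null(path)) path <- file.path(dir, "report.md")
  lines <- c("# Codon usage analysis report", "")
  bad <- character()
  for (f in names(mf$files)) {
    p <- file.path(dir, f)
    if (!file.exists(p) || unname(tools::md5sum(p)) != mf$files[[f]])
      bad <- c(bad, f)
  }
  if (length(bad)) {
    warning("manifest checksum mismatch: ", paste(bad, collapse = ", "),
            call. = FALSE)
    lines <- c(lines, paste0("**INTEGRITY WARNING**: checksums differ from ",
                             "the manifest for: ", paste(bad, collapse = ", ")),
               "")
  }
  grp <- unlist(mf$groups)
  lines <- c(lines,
             sprintf("Analyzed %s coding sequences (%s) with seed %s.",
                     mf$n_sequences,
                     paste(sprintf("%s: %s", names(grp), grp), collapse = ", "),
                     mf$seed), "")
  rd <- function(f) utils::read.delim(file.path(dir, f), check.names = FALSE)
  if (file.exists(file.path(dir, "classification.tsv"))) {
    cl <- rd("classification.tsv")
    lines <- c(lines, "## Codon classification (see classification.tsv)", "")
    nset <- function(z) {
      if (length(z) != 1 || is.na(z) || !nzchar(z)) 0L
      else length(strsplit(as.character(z), " ")[[1]])
    }
    for (i in seq_len(nrow(cl))) {
      nover <- nset(cl$over_represented[i])
      nunder <- nset(cl$under_represented[i])
      lines <- c(lines, sprintf(
        "- %s: %d over-represented and %d under-represented codons.",
        cl$scope[i], nover, nunder))
    }
    lines <- c(lines, "")
  }
  if (file.exists(file.path(dir, "neutrality_fit.tsv"))) {
    nf <- rd("neutrality_fit.tsv")
    ov <- nf[nf$scope == "overall", ]
    lines <- c(lines, "## Neutrality plot (see neutrality_fit.tsv)", "",
               sprintf(paste0("The overall regression of GC12 on GC3 gave a ",
                              "slope of %s, which indicates that natural ",
                              "selection plays a major role (%s%%) in ",
                              "shaping the codon usage pattern, against ",
                              "%s%% attributable to mutation pressure."),
                       ov$slope, ov$selection_pct, ov$mutation_pct), "")
  }
  if (file.exists(file.path(dir, "pca_variance.tsv"))) {
    pv <- rd("pca_variance.tsv")
    lines <- c(lines, "## PCA (see pca_scores.tsv, pca_variance.tsv,",
               "pca_loadings.tsv)", "",
               sprintf("The first two components account for %s%% and %s%% of total variation.",
                       pv$var_explained_pct[1],
                       if (nrow(pv) > 1) pv$var_explained_pct[2] else 0), "")
  }
  if (file.exists(file.path(dir, "cai_groups.tsv"))) {
    cg <- rd("cai_groups.tsv")
    lines <- c(lines, "## CAI group comparison (see cai_groups.tsv, cai_pairwise_p.tsv)", "",
               paste(sprintf("- %s: mean CAI %s (letter %s)",
                             cg$group, cg$mean_cai, cg$letter),
                     collapse = "\n"), "")
  } else {
    lines <- c(lines, "## CAI group comparison", "",
               "Not applicable (no reference table or fewer than two groups).",
               "")
  }
  lines <- c(lines, "## Artifacts", "",
             paste0("- ", names(mf$files)), "- config.yaml", "- manifest.json")
  writeLines(lines, path)
  invisible(path)
}
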