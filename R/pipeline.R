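#' Load a pipeline run configuration
#'
#' Accepts a list, a JSON file or a YAML file. Required keys: input
#' paths `ped`, `vcf`, `annotations`; optional `lod_curve`,
#' `per_family_lod`, `gene_intervals`, `replication`; `out_dir`, `seed`,
#' `n_sims` and threshold overrides (`af_very_rare`, `af_rare`,
#' `lfam_min_affected`, `sharing_fraction`, `unaffected_fraction`,
#' `lod_threshold`).
#'
#' @param config list or path.
#' @return normalized config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required for YAML configs")
      yaml::read_yaml(config)
    }
  }
  defaults <- list(seed = 1L, n_sims = 10000L, af_very_rare = 0.005,
                   af_rare = 0.05, lfam_min_affected = 4L,
                   lod_threshold = 1.5, out_dir = "famrvar_run")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in c("ped", "vcf", "annotations"))
    if (is.null(config[[k]])) stop("config missing required path: ", k)
  config
}

#' Run the full prioritization pipeline
#'
#' Executes QC, orientation and both prioritization strategies — shared
#' rare damaging variants under linkage loci across contributing
#' families, and very rare damaging variants shared within lfams — then
#' segregation filtering, gene-drop enrichment, case/control
#' replication, the correlation-informed multiple-testing budget and the
#' final significant-variant list. Per-stage variant counts are logged
#' via `message()` and returned.
#'
#' @param config see [load_run_config()].
#' @return list of stage outputs (invisibly also written as TSV/JSON
#'   reports under `out_dir`).
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_counts <- list()
  note <- function(stage, n) {
    log_counts[[stage]] <<- n
    message(sprintf("[famrvar] %-24s %6d", stage, n))
  }

  cohort <- read_pedigree(cfg$ped)
  vs <- read_vcf(cfg$vcf)
  vs <- attach_annotations(vs, cfg$annotations)
  note("variants_read", nrow(vs$variants))

  vs <- mask_failing_genotypes(vs)
  vqc <- variant_qc(vs)
  vs <- vs_subset(vs, keys = vqc$key[vqc$pass])
  note("variants_after_qc", nrow(vs$variants))
  vs <- orient_to_minor_allele(vs)

  # strategy 1: linkage-locus sharing across contributing families
  linkage_hits <- NULL
  if (!is.null(cfg$lod_curve) && !is.null(cfg$per_family_lod) &&
      !is.null(cfg$gene_intervals)) {
    lod_curve <- utils::read.delim(cfg$lod_curve)
    per_family_lod <- utils::read.delim(cfg$per_family_lod)
    genes <- utils::read.delim(cfg$gene_intervals)
    loci <- select_loci(lod_curve, cfg$lod_threshold)
    note("linkage_loci", nrow(loci))
    if (nrow(loci) > 0) {
      linkage_hits <- unique(rbind(
        linkage_shared_variants(vs, loci, cohort, per_family_lod, genes,
                                "IBD", af_max = cfg$af_rare),
        linkage_shared_variants(vs, loci, cohort, per_family_lod, genes,
                                "CD", af_max = cfg$af_rare)))
      linkage_hits <- linkage_hits[!duplicated(linkage_hits$key), ]
    }
  }
  n_linkage <- if (is.null(linkage_hits)) 0L else nrow(linkage_hits)
  note("linkage_variants", n_linkage)

  # strategy 2: very rare damaging variants shared within lfams
  fam_ibd <- prioritize_rare_family_variants(
    vs, cohort, "IBD", cfg$lfam_min_affected, cfg$af_very_rare)
  fam_cd <- prioritize_rare_family_variants(
    vs, cohort, "CD", cfg$lfam_min_affected, cfg$af_very_rare)
  fam_hits <- rbind(fam_ibd, fam_cd)
  fam_keys <- unique(fam_hits$key)
  note("family_variants", length(fam_keys))

  # segregation against unaffecteds in families with >= 2 eligible
  seg <- list()
  for (i in seq_len(nrow(fam_hits))) {
    for (f in strsplit(fam_hits$lfams[i], ",")[[1]]) {
      fam <- get_family(cohort, f)
      seg[[length(seg) + 1]] <-
        segregation_filter(vs, fam_hits$key[i], fam, fam_hits$phenotype[i])
    }
  }
  seg <- if (length(seg)) do.call(rbind, seg) else NULL
  n_seg <- if (is.null(seg)) 0L else
    sum(!seg$skipped & seg$passes_third, na.rm = TRUE)
  note("segregation_pass", n_seg)

  # gene dropping per family-prioritized variant (IBD and CD datasets)
  v <- vs$variants
  gd <- NULL
  if (length(fam_keys) > 0) {
    gd <- do.call(rbind, lapply(fam_keys, function(key) {
      j <- match(key, v$key)
      caf <- control_af(v$af_aj[j], v$af_nfe[j], v$af_paj[j],
                        if ("af_aj_wgs" %in% names(v)) v$af_aj_wgs[j] else NA,
                        context = "genedrop")
      index_fam <- strsplit(fam_hits$lfams[match(key, fam_hits$key)],
                            ",")[[1]][1]
      row <- lapply(c("IBD", "CD"), function(ph) {
        cf <- genedrop_config(n_sims = cfg$n_sims,
                              seed = derive_seed(cfg$seed,
                                                 paste0(key, ph)),
                              exclude_family = index_fam, phenotype = ph)
        res <- tryCatch(genedrop_test(vs, key, cohort, caf$control_af, cf),
                        error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(key = key, phenotype = ph,
                   control_af = caf$control_af,
                   observed_af = res$observed_af, p = res$p_value,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, row)
    }))
  }

  # case/control replication for every prioritized variant
  repl_min <- NULL
  all_keys <- union(fam_keys, if (n_linkage) linkage_hits$key else NULL)
  cc_matrix <- NULL
  if (!is.null(cfg$replication) && length(all_keys) > 0) {
    repl <- utils::read.delim(cfg$replication)
    repl <- repl[repl$key %in% all_keys, ]
    if (nrow(repl) > 0) {
      per <- lapply(split(repl, repl$key), function(d) {
        rows <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
          ft <- fisher_allele_test(d$case_alt[i], d$case_ref[i],
                                   d$ctrl_alt[i], d$ctrl_ref[i])
          data.frame(key = d$key[i], phenotype = d$phenotype[i],
                     p = ft$p, or = ft$or,
                     case_af = d$case_alt[i] / (d$case_alt[i] + d$case_ref[i]),
                     control_af = d$ctrl_alt[i] / (d$ctrl_alt[i] + d$ctrl_ref[i]),
                     stringsAsFactors = FALSE)
        }))
        min_phenotype_result(rows)
      })
      repl_min <- do.call(rbind, per)
      wide <- do.call(rbind, lapply(split(repl, repl$key), function(d) {
        p <- vapply(c("IBD", "CD", "UC"), function(ph) {
          i <- match(ph, d$phenotype)
          if (is.na(i)) NA_real_ else
            fisher_allele_test(d$case_alt[i], d$case_ref[i],
                               d$ctrl_alt[i], d$ctrl_ref[i])$p
        }, 0)
        p
      }))
      cc_matrix <- wide
    }
  }

  # effective dataset counts (case/control; gene dropping)
  eff_cc <- if (!is.null(cc_matrix) && nrow(cc_matrix) >= 3) {
    tryCatch(effective_dataset_count(cc_matrix)$n_effective,
             error = function(e) ncol(cc_matrix),
             warning = function(w) ncol(cc_matrix))
  } else 3L
  gd_matrix <- if (!is.null(gd)) {
    m <- do.call(rbind, lapply(split(gd, gd$key), function(d)
      vapply(c("IBD", "CD"), function(ph) {
        i <- match(ph, d$phenotype)
        if (is.na(i)) NA_real_ else d$p[i]
      }, 0)))
    m
  } else NULL
  eff_gd <- if (!is.null(gd_matrix) && nrow(gd_matrix) >= 3) {
    tryCatch(effective_dataset_count(gd_matrix)$n_effective,
             error = function(e) ncol(gd_matrix),
             warning = function(w) ncol(gd_matrix))
  } else 2L

  budget <- if (n_linkage + length(fam_keys) > 0)
    test_budget(n_linkage, length(fam_keys), eff_cc, eff_gd) else NULL

  # combine the evidence per variant: min over replication and gene drop
  sig <- NULL
  if (!is.null(budget)) {
    min_p <- data.frame(key = all_keys, min_p = NA_real_,
                        stringsAsFactors = FALSE)
    if (!is.null(repl_min)) {
      i <- match(repl_min$key, min_p$key)
      min_p$min_p[i] <- repl_min$p
    }
    if (!is.null(gd)) {
      gmin <- tapply(gd$p, gd$key, min)
      i <- match(names(gmin), min_p$key)
      min_p$min_p[i] <- pmin(min_p$min_p[i], gmin, na.rm = TRUE)
    }
    sig <- count_significant(min_p, budget$alpha)
    note("significant_variants", sig$n)
  }

  out <- list(cohort = cohort, variant_qc = vqc,
              linkage_hits = linkage_hits, family_hits = fam_hits,
              segregation = seg, genedrop = gd, replication = repl_min,
              budget = budget, significant = sig, counts = log_counts)
  # reports
  fp <- function(x) file.path(cfg$out_dir, x)
  if (!is.null(linkage_hits)) write_report(linkage_hits, fp("linkage_variants.tsv"))
  write_report(fam_hits, fp("family_variants.tsv"))
  if (!is.null(seg)) write_report(seg, fp("segregation.tsv"))
  if (!is.null(gd)) write_report(gd, fp("genedrop.tsv"))
  if (!is.null(repl_min)) write_report(repl_min, fp("replication_min.tsv"))
  if (!is.null(budget))
    jsonlite::write_json(
      list(total_tests = budget$total_tests, alpha = budget$alpha,
           eff_cc_datasets = budget$eff_cc_datasets,
           eff_gd_datasets = budget$eff_gd_datasets,
           significant = sig$keys, counts = log_counts),
      fp("summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
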