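#' Simulation configuration for a synthetic multiplex-family study
#'
#' Defaults emulate the structure of a multiplex Ashkenazi IBD exome
#' study: ~200 multiplex families (a subset large three-generation
#' pedigrees eligible as lfams), a few hundred sporadic cases, a
#' founder-AF spectrum concentrated below 0.05, a logistic liability
#' model with a shared familial component, and case/control replication
#' cohorts of the published sizes.
#'
#' @param seed RNG seed.
#' @param n_families multiplex families (default 60; scale down from 199
#'   for test-speed, scale up freely).
#' @param n_lfams families forced (by liability boost + ascertainment
#'   rejection) to have >= 4 sequenced affecteds (default 8).
#' @param n_sporadic_cases,n_controls singleton counts.
#' @param n_variants background variant count.
#' @param founder_af_range background founder AFs are drawn log-uniform
#'   in this range (default 0.0005-0.05).
#' @param prevalence baseline affection probability (default 0.01).
#' @param familial_sd sd of the shared per-family liability term
#'   (default 1.5); lfam-designated families get `lfam_boost` added to
#'   their liability instead of a random draw.
#' @param lfam_boost liability shift for designated lfams (default 5).
#' @param subtype_probs CD/UC/IBDU proportions among affecteds.
#' @param p_seq_affected,p_seq_unaffected sequencing probabilities.
#' @param mean_depth mean read depth for AD synthesis.
#' @param planted data.frame of planted variants: columns `key` (or
#'   chrom/pos/ref/alt), `founder_af`, `n_target_families`,
#'   `carrier_fraction` (default 0.8), `consequence`, `gene`.
#' @param replication data.frame of replication cohorts: `phenotype`,
#'   `n_cases`, `n_controls` (defaults: IBD 1867/3616, CD 1286/3035,
#'   UC 544/3035).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_families = 60L, n_lfams = 8L,
                       n_sporadic_cases = 80L, n_controls = 60L,
                       n_variants = 40L,
                       founder_af_range = c(5e-4, 0.05),
                       prevalence = 0.01, familial_sd = 1.5,
                       lfam_boost = 5, subtype_probs = c(CD = 0.55,
                                                         UC = 0.35,
                                                         IBDU = 0.10),
                       p_seq_affected = 0.9, p_seq_unaffected = 0.15,
                       mean_depth = 40,
                       planted = NULL,
                       replication = data.frame(
                         phenotype = c("IBD", "CD", "UC"),
                         n_cases = c(1867L, 1286L, 544L),
                         n_controls = c(3616L, 3035L, 3035L))) {
  stopifnot(prevalence > 0, prevalence < 1,
            abs(sum(subtype_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one multiplex pedigree
#'
#' Three-generation structure: a founder couple, `sibship` children each
#' married to an unrelated founder spouse, and `sibship` grandchildren
#' per couple. Two generations drop the grandchild layer.
#'
#' @param family_id family id string.
#' @param generations 2 or 3.
#' @param sibship children per couple (scalar or length-2 for the two
#'   layers).
#' @return a `family_ped` (phenotypes `unknown`, `sequenced` FALSE —
#'   see [assign_phenotypes()]).
#' @export
simulate_pedigree <- function(family_id, generations = 3L, sibship = 3L) {
  if (generations < 2) stop("need at least two generations")
  sib <- rep_len(sibship, 2)
  if (any(sib < 1)) stop("sibship sizes must be positive")
  mk <- function(n) sprintf("%s_%02d", family_id, n)
  ind <- data.frame(id = c(mk(1), mk(2)), father_id = NA_character_,
                    mother_id = NA_character_,
                    sex = c("male", "female"), stringsAsFactors = FALSE)
  nxt <- 3
  gen2 <- character(0)
  for (s in seq_len(sib[1])) {
    child <- mk(nxt); nxt <- nxt + 1
    sexes <- c("male", "female")
    csex <- sexes[1 + (s %% 2)]
    ind <- rbind(ind, data.frame(id = child, father_id = mk(1),
                                 mother_id = mk(2), sex = csex))
    gen2 <- c(gen2, child)
  }
  if (generations >= 3) {
    for (child in gen2) {
      spouse <- mk(nxt); nxt <- nxt + 1
      csex <- ind$sex[ind$id == child]
      ssex <- if (csex == "male") "female" else "male"
      ind <- rbind(ind, data.frame(id = spouse, father_id = NA_character_,
                                   mother_id = NA_character_, sex = ssex))
      fa <- if (csex == "male") child else spouse
      mo <- if (csex == "male") spouse else child
      for (s in seq_len(sib[2])) {
        gc <- mk(nxt); nxt <- nxt + 1
        ind <- rbind(ind, data.frame(id = gc, father_id = fa,
                                     mother_id = mo,
                                     sex = c("male", "female")[1 + (s %% 2)]))
      }
    }
  }
  ind$family_id <- family_id
  ind$phenotype <- "unknown"
  ind$sequenced <- FALSE
  as_family_ped(ind)
}

#' Assign phenotypes under a logistic liability model
#'
#' logit P(affected) = logit(prevalence) + sum(log OR x dosage) +
#' familial term (shared per family). Affecteds draw a subtype from
#' `subtype_probs`; everyone else is `unaffected`. Sequencing flags are
#' drawn per phenotype.
#'
#' @param ind family individual table.
#' @param dosage named list / matrix of planted-variant dosages per
#'   individual (or NULL).
#' @param log_or per-variant log odds ratios aligned with `dosage`
#'   columns.
#' @param familial family-level liability shift.
#' @param config a [sim_config()].
#' @return the table with `phenotype` and `sequenced` filled.
#' @export
assign_phenotypes <- function(ind, dosage = NULL, log_or = NULL,
                              familial = 0, config = sim_config()) {
  eta <- stats::qlogis(config$prevalence) + familial
  if (!is.null(dosage) && length(log_or) > 0) {
    dosage <- as.matrix(dosage)
    eta <- eta + as.vector(dosage[ind$id, , drop = FALSE] %*% log_or)
  }
  affected <- stats::runif(nrow(ind)) < stats::plogis(eta)
  subtype <- sample(names(config$subtype_probs), nrow(ind), replace = TRUE,
                    prob = config$subtype_probs)
  ind$phenotype <- ifelse(affected, subtype, "unaffected")
  ind$sequenced <- stats::runif(nrow(ind)) <
    ifelse(affected, config$p_seq_affected, config$p_seq_unaffected)
  ind
}

# sample one multiplex family: structure + phenotypes, with ascertainment
# (>= 2 sequenced affecteds; >= 4 for designated lfams)
.sim_family <- function(family_id, config, force_lfam = FALSE,
                        max_tries = 1000L) {
  gens <- if (force_lfam) 3L else sample(2:3, 1)
  sib <- if (force_lfam) sample(3:4, 1) else sample(2:4, 1)
  fam <- simulate_pedigree(family_id, gens, sib)
  need <- if (force_lfam) 4L else 2L
  for (try in seq_len(max_tries)) {
    # redraw the familial liability each attempt: ascertainment samples
    # family-level risk jointly with the affection pattern
    familial <- if (force_lfam) config$lfam_boost else
      abs(stats::rnorm(1, 0, config$familial_sd))
    out <- assign_phenotypes(fam, familial = familial, config = config)
    n_aff <- sum(out$sequenced & pheno_matches(out$phenotype, "IBD"))
    if (n_aff >= need) return(out)
  }
  stop("ascertainment failed for family ", family_id)
}

#' Simulate a complete synthetic study cohort
#'
#' Families are generated and ascertained (multiplex: at least two
#' sequenced affecteds; designated lfams: at least four), then sporadic
#' cases and controls are appended as singletons.
#'
#' @param config a [sim_config()].
#' @return a `cohort`; lfam-designated family ids in attribute
#'   `lfam_designated`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  fams <- list()
  for (i in seq_len(config$n_families)) {
    fams[[i]] <- .sim_family(sprintf("F%03d", i), config,
                             force_lfam = i <= config$n_lfams)
  }
  singles <- function(prefix, n, phenotype) {
    if (n == 0) return(NULL)
    data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
               family_id = sprintf("%s%04d", prefix, seq_len(n)),
               father_id = NA_character_, mother_id = NA_character_,
               sex = sample(c("male", "female"), n, replace = TRUE),
               phenotype = phenotype, sequenced = TRUE,
               stringsAsFactors = FALSE)
  }
  spor <- singles("S", config$n_sporadic_cases, "IBDU")
  if (!is.null(spor))
    spor$phenotype <- sample(names(config$subtype_probs),
                             nrow(spor), replace = TRUE,
                             prob = config$subtype_probs)
  ctrl <- singles("C", config$n_controls, "unaffected")
  ind <- do.call(rbind, c(lapply(fams, as.data.frame), list(spor, ctrl)))
  cohort <- new_cohort(ind[, c("id", "family_id", "father_id", "mother_id",
                               "sex", "phenotype", "sequenced")])
  attr(cohort, "lfam_designated") <-
    sprintf("F%03d", seq_len(config$n_lfams))
  cohort
}

# default annotation sampler for background variants
.sim_annotation <- function(n, af, gene) {
  consequence <- sample(c("missense", "frameshift", "stop_gain",
                          "splice_acceptor", "splice_donor", "other"),
                        n, replace = TRUE,
                        prob = c(0.55, 0.08, 0.08, 0.04, 0.05, 0.20))
  carol <- ifelse(consequence == "missense",
                  sample(c("damaging", "benign"), n, replace = TRUE,
                         prob = c(0.6, 0.4)), NA)
  cadd <- round(stats::rgamma(n, shape = 4, scale = 6), 1)
  jitter <- function(x) pmin(1, pmax(0, x * exp(stats::rnorm(n, 0, 0.15))))
  data.frame(gene = gene, consequence = consequence, carol = carol,
             cadd = cadd, af_aj = jitter(af), af_nfe = jitter(af),
             af_paj = jitter(af), af_aj_wgs = jitter(af),
             stringsAsFactors = FALSE)
}

#' Simulate genotypes (and quality fields) for a cohort
#'
#' Background variants get founder AFs log-uniform over the configured
#' range; genotypes descend by gene dropping ([drop_family()]).
#' Planted variants are written directly into their target families:
#' `carrier_fraction` of each target lfam's sequenced affecteds are set
#' heterozygous (emulating a high-penetrance founder variant), everyone
#' else non-carrier. Depth/GQ fields are synthesized (depth ~ Poisson,
#' alt reads ~ Binomial at the dosage-expected alt fraction).
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param config a [sim_config()].
#' @return list: `vs` (a `variant_set` with annotations attached),
#'   `truth` (per-variant founder AF and planting detail).
#' @export
simulate_genotypes <- function(cohort, config = sim_config()) {
  set.seed(derive_seed(config$seed, "genotypes"))
  ind <- cohort$individuals
  n_bg <- config$n_variants
  af <- exp(stats::runif(n_bg, log(config$founder_af_range[1]),
                         log(config$founder_af_range[2])))
  pos <- sort(sample(1e6:5e7, n_bg))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_bg, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  meta <- data.frame(
    key = variant_key("1", pos, ref, alt), chrom = "1", pos = pos,
    ref = ref, alt = alt, vqsr_tranche = round(stats::runif(n_bg, 90, 99.5), 2),
    is_snp = TRUE, stringsAsFactors = FALSE)
  ann <- .sim_annotation(n_bg, af, gene = sprintf("GENE%03d", seq_len(n_bg)))
  meta <- cbind(meta, ann)
  truth <- data.frame(key = meta$key, founder_af = af, planted = FALSE,
                      target_families = "", stringsAsFactors = FALSE)

  geno <- matrix(0L, nrow(ind), n_bg, dimnames = list(ind$id, meta$key))
  for (f in unique(ind$family_id)) {
    rows <- ind$family_id == f
    if (sum(rows) == 1) {
      geno[rows, ] <- stats::rbinom(n_bg, 2L, af)
    } else {
      fam <- as_family_ped(ind[rows, ])
      for (j in seq_len(n_bg)) {
        geno[fam$id, j] <- drop_family(fam, af[j], 1L)[, 1]
      }
    }
  }

  # planted variants: direct carrier assignment in target lfams
  if (!is.null(config$planted) && nrow(config$planted) > 0) {
    pl <- config$planted
    lfams <- attr(cohort, "lfam_designated")
    for (i in seq_len(nrow(pl))) {
      cf <- pl$carrier_fraction[i] %||% 0.8
      if (is.na(cf)) cf <- 0.8
      nt <- pl$n_target_families[i]
      targets <- lfams[seq_len(min(nt, length(lfams)))]
      g <- rep(0L, nrow(ind))
      for (f in targets) {
        fam_aff <- ind$id[ind$family_id == f & ind$sequenced &
                            pheno_matches(ind$phenotype, "IBD")]
        n_car <- max(2L, ceiling(cf * length(fam_aff)))
        carriers <- fam_aff[seq_len(min(n_car, length(fam_aff)))]
        g[match(carriers, ind$id)] <- 1L
      }
      geno <- cbind(geno, g)
      pkey <- pl$key[i]
      paf <- pl$founder_af[i]
      meta <- rbind(meta, data.frame(
        key = pkey, chrom = sub("_.*", "", pkey),
        pos = as.integer(strsplit(pkey, "_")[[1]][2]),
        ref = strsplit(pkey, "_")[[1]][3],
        alt = strsplit(pkey, "_")[[1]][4],
        vqsr_tranche = 95, is_snp = TRUE,
        gene = pl$gene[i] %||% sprintf("PGENE%d", i),
        consequence = pl$consequence[i] %||% "frameshift",
        carol = "damaging", cadd = 35,
        af_aj = paf, af_nfe = paf, af_paj = paf, af_aj_wgs = paf,
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        key = pkey, founder_af = paf, planted = TRUE,
        target_families = paste(targets, collapse = ","),
        stringsAsFactors = FALSE))
    }
    colnames(geno) <- meta$key
  }

  n_var <- ncol(geno)
  depth <- matrix(stats::rpois(length(geno), config$mean_depth),
                  nrow(geno), n_var)
  alt_frac <- matrix(c(0.01, 0.5, 0.99)[geno + 1L], nrow(geno), n_var)
  ad_alt <- matrix(stats::rbinom(length(geno), as.vector(depth),
                                 as.vector(alt_frac)), nrow(geno), n_var)
  ad_ref <- depth - ad_alt
  gq <- matrix(as.integer(pmin(99, pmax(0, round(stats::rnorm(length(geno), 70, 15))))),
               nrow(geno), n_var)
  vs <- variant_set(meta, geno, gq, ad_ref, ad_alt)
  list(vs = vs, truth = truth)
}

#' Simulate a per-family LOD table and LOD curve with a planted locus
#'
#' Families whose sequenced affecteds share a named variant receive a
#' positive mean LOD over the planted locus; the others are centred near
#' zero. The genome-wide LOD curve is flat noise with a triangular peak
#' of height `peak_lod` at the locus.
#'
#' @param cohort a `cohort`.
#' @param vs a `variant_set` (carrier sharing defines contributing
#'   families).
#' @param planted_key variant key marking the locus (or NULL for a null
#'   table).
#' @param chrom,start_bp,end_bp locus position (defaults bracket the
#'   planted variant).
#' @param peak_lod height of the planted peak (default 2.074).
#' @param seed RNG seed.
#' @return list: `lod_curve` (chrom, bp, cM, lod), `per_family_lod`
#'   (family_id, chrom, start_bp, end_bp, lod), `locus`.
#' @export
simulate_lod_table <- function(cohort, vs, planted_key = NULL,
                               chrom = "1", start_bp = NULL,
                               end_bp = NULL, peak_lod = 2.074,
                               seed = 1L) {
  set.seed(derive_seed(seed, "lod"))
  grid_bp <- seq(1e6, 5e7, by = 5e5)
  curve <- data.frame(chrom = chrom, bp = grid_bp, cM = grid_bp / 1e6,
                      lod = pmax(-1, stats::rnorm(length(grid_bp), -0.2, 0.3)))
  per_fam <- NULL
  locus <- NULL
  if (!is.null(planted_key)) {
    j <- match(planted_key, vs$variants$key)
    if (is.na(j)) stop("unknown planted key")
    vpos <- vs$variants$pos[j]
    start_bp <- start_bp %||% (vpos - 2e6)
    end_bp <- end_bp %||% (vpos + 2e6)
    in_locus <- grid_bp >= start_bp & grid_bp <= end_bp
    centre <- (start_bp + end_bp) / 2
    tri <- 1 - abs(grid_bp - centre) / ((end_bp - start_bp) / 2)
    curve$lod[in_locus] <- peak_lod * pmax(tri[in_locus], 0.75)
    ind <- cohort$individuals
    fams <- family_ids(cohort)
    share <- vapply(fams, function(f) {
      aff <- ind$id[ind$family_id == f & ind$sequenced &
                      pheno_matches(ind$phenotype, "IBD")]
      sum(vs$geno[aff, j] >= 1, na.rm = TRUE) >= 2
    }, TRUE)
    per_fam <- data.frame(
      family_id = fams, chrom = chrom, start_bp = start_bp,
      end_bp = end_bp,
      lod = ifelse(share, stats::rnorm(length(fams), 0.5, 0.1),
                   stats::rnorm(length(fams), -0.2, 0.04)),
      stringsAsFactors = FALSE)
    locus <- data.frame(chrom = chrom, start_bp = start_bp,
                        end_bp = end_bp, peak_lod = peak_lod)
  }
  list(lod_curve = curve, per_family_lod = per_fam, locus = locus)
}

#' Simulate a case/control replication allele-count table
#'
#' For each variant and phenotype cohort, case AF is derived from the
#' control AF and the true odds ratio; allele counts are Binomial
#' draws. Variants whose total alternate count across cases and controls
#' is below two are omitted, mirroring replication panels that drop
#' singleton sites.
#'
#' @param variant_specs data.frame: `key`, `control_af`, `true_or`.
#' @param cohorts data.frame: `phenotype`, `n_cases`, `n_controls`.
#' @param seed RNG seed.
#' @return data.frame: `key`, `phenotype`, `case_alt`, `case_ref`,
#'   `ctrl_alt`, `ctrl_ref`.
#' @export
simulate_replication <- function(variant_specs, cohorts, seed = 1L) {
  set.seed(derive_seed(seed, "replication"))
  out <- list()
  for (i in seq_len(nrow(variant_specs))) {
    af0 <- variant_specs$control_af[i]
    or <- variant_specs$true_or[i]
    if (af0 <= 0) next
    odds <- or * af0 / (1 - af0)
    af1 <- odds / (1 + odds)
    for (r in seq_len(nrow(cohorts))) {
      na <- 2L * cohorts$n_cases[r]; nc <- 2L * cohorts$n_controls[r]
      ca <- stats::rbinom(1, na, af1)
      oa <- stats::rbinom(1, nc, af0)
      if (ca + oa < 2) next
      out[[length(out) + 1]] <- data.frame(
        key = variant_specs$key[i], phenotype = cohorts$phenotype[r],
        case_alt = ca, case_ref = na - ca, ctrl_alt = oa,
        ctrl_ref = nc - oa, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(key = character(0), phenotype = character(0),
                      case_alt = integer(0), case_ref = integer(0),
                      ctrl_alt = integer(0), ctrl_ref = integer(0)))
  do.call(rbind, out)
}

#' Simulate the complete study input bundle
#'
#' Runs [simulate_cohort()], [simulate_genotypes()],
#' [simulate_lod_table()] (locus anchored at the first planted variant,
#' if any) and [simulate_replication()], returning every input the
#' analysis pipeline consumes plus the generating truth.
#'
#' @param config a [sim_config()].
#' @return list: `cohort`, `vs`, `truth`, `lod`, `replication`,
#'   `gene_intervals`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  gt <- simulate_genotypes(cohort, config)
  planted_key <- if (any(gt$truth$planted))
    gt$truth$key[gt$truth$planted][1] else NULL
  lod <- simulate_lod_table(cohort, gt$vs, planted_key,
                            seed = derive_seed(config$seed, "lodseed"))
  v <- gt$vs$variants
  caf <- control_af(v$af_aj, v$af_nfe, v$af_paj, v$af_aj_wgs)
  specs <- data.frame(key = v$key, control_af = caf$control_af,
                      true_or = 1, stringsAsFactors = FALSE)
  repl <- simulate_replication(specs, config$replication,
                               seed = derive_seed(config$seed, "repl"))
  gene_intervals <- data.frame(
    gene = v$gene, chrom = v$chrom, start = pmax(1, v$pos - 5e4),
    end = v$pos + 5e4, stringsAsFactors = FALSE)
  gene_intervals <- gene_intervals[!duplicated(gene_intervals$gene), ]
  list(cohort = cohort, vs = gt$vs, truth = gt$truth, lod = lod,
       replication = repl, gene_intervals = gene_intervals,
       config = config)
}

#' Write a simulated study to disk as plain-text pipeline inputs
#'
#' Emits `cohort.ped`, `genotypes.vcf`, `annotations.tsv`,
#' `lod_curve.tsv`, `per_family_lod.tsv`, `gene_intervals.tsv`,
#' `replication.tsv` and `truth.json` under `dir`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_pedigree(study$cohort, fp("cohort.ped"))
  write_vcf(study$vs, fp("genotypes.vcf"))
  ann_cols <- c("key", "gene", "consequence", "carol", "cadd",
                "af_aj", "af_nfe", "af_paj", "af_aj_wgs")
  utils::write.table(study$vs$variants[, ann_cols], fp("annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$lod$lod_curve, fp("lod_curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(study$lod$per_family_lod))
    utils::write.table(study$lod$per_family_lod, fp("per_family_lod.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$gene_intervals, fp("gene_intervals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$replication, fp("replication.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
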