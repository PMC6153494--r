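# Fixture builders shared across test files. Everything is constructed in
# code; no binary fixtures.

# nuclear family: two founders, `n_children` children; phenotypes given as
# a vector for the children ("CD", "UC", "IBDU", "unaffected"), parents
# default unaffected
nuclear_family <- function(fid = "FAM1", n_children = 2,
                           child_pheno = rep("CD", n_children),
                           parent_pheno = c("unaffected", "unaffected"),
                           sequenced = TRUE) {
  ids <- c(paste0(fid, "_p1"), paste0(fid, "_p2"),
           paste0(fid, "_c", seq_len(n_children)))
  data.frame(
    id = ids, family_id = fid,
    father_id = c(NA, NA, rep(ids[1], n_children)),
    mother_id = c(NA, NA, rep(ids[2], n_children)),
    sex = c("male", "female",
            rep(c("male", "female"), length.out = n_children)),
    phenotype = c(parent_pheno, child_pheno),
    sequenced = rep_len(sequenced, n_children + 2),
    stringsAsFactors = FALSE)
}

# cohort made of nuclear families described by a list of child phenotype
# vectors
make_cohort <- function(child_pheno_list, ...) {
  tabs <- lapply(seq_along(child_pheno_list), function(i)
    nuclear_family(sprintf("FAM%d", i),
                   n_children = length(child_pheno_list[[i]]),
                   child_pheno = child_pheno_list[[i]], ...))
  new_cohort(do.call(rbind, tabs))
}

# minimal variant_set: dosage matrix (samples x variants) + optional
# annotation columns
make_vs <- function(geno, af = 0.001, consequence = "frameshift",
                    carol = NA, cadd = 35, gene = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  nv <- ncol(geno)
  pos <- pos %||% (1000 + seq_len(nv))
  v <- data.frame(
    key = variant_key("1", pos, "A", "T"), chrom = "1", pos = pos,
    ref = "A", alt = "T", vqsr_tranche = 95, is_snp = TRUE,
    gene = gene %||% paste0("G", seq_len(nv)),
    consequence = rep_len(consequence, nv), carol = rep_len(carol, nv),
    cadd = rep_len(cadd, nv), af_aj = rep_len(af, nv),
    af_nfe = rep_len(af, nv), af_paj = rep_len(af, nv),
    af_aj_wgs = rep_len(af, nv), stringsAsFactors = FALSE)
  variant_set(v, geno)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# three-generation pedigree used by the segregation-probability tests:
# founder couple -> two children married to founder spouses -> grandkids
three_gen_family <- function(fid = "G1", grandkids_per_branch = 2) {
  ind <- data.frame(
    id = c("gf", "gm", "s1", "sp1", "s2", "sp2"),
    father_id = c(NA, NA, "gf", NA, "gf", NA),
    mother_id = c(NA, NA, "gm", NA, "gm", NA),
    sex = c("male", "female", "male", "female", "female", "male"),
    stringsAsFactors = FALSE)
  for (b in 1:2) {
    fa <- if (b == 1) "s1" else "sp2"
    mo <- if (b == 1) "sp1" else "s2"
    for (g in seq_len(grandkids_per_branch)) {
      ind <- rbind(ind, data.frame(
        id = sprintf("k%d%d", b, g), father_id = fa, mother_id = mo,
        sex = c("male", "female")[1 + g %% 2]))
    }
  }
  ind$id <- paste0(fid, "_", ind$id)
  ind$father_id <- ifelse(is.na(ind$father_id), NA,
                          paste0(fid, "_", ind$father_id))
  ind$mother_id <- ifelse(is.na(ind$mother_id), NA,
                          paste0(fid, "_", ind$mother_id))
  ind$family_id <- fid
  ind$phenotype <- "unaffected"
  ind$sequenced <- TRUE
  as_family_ped(ind)
}
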