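# File formats and orchestration: VCF / dosage-TSV genotypes, phenotype
# CSV, GWAS summary-statistic TSV, weight-table and frequency-table TSV,
# baseline incidence CSV, YAML run configuration, and the end-to-end
# pipeline with a reproducibility manifest.

#' Published PHS weight table
#'
#' The 31 SNP log hazard-ratio weights plus the APOE e2 (-0.47) and e4
#' (1.03) allele terms that define the Alzheimer polygenic hazard score,
#' with their conditional -log10 p-values in the joint model.
#'
#' @return `phs_beta_table` data frame.
#' @export
phs_weights_ad <- function() {
  out <- utils::read.delim(system.file("extdata", "phs_weights_ad.tsv",
                                       package = "polyhaz"))
  class(out) <- c("phs_beta_table", "data.frame")
  out
}

#' US population annualized incidence baseline
#'
#' Community-sampled US annualized Alzheimer incidence (percent per year)
#' at five-year knots from age 60 to 95.
#'
#' @return `phs_baseline` table.
#' @export
us_ad_incidence <- function() {
  tab <- utils::read.csv(system.file("extdata", "us_ad_incidence.csv",
                                     package = "polyhaz"))
  baseline_incidence(tab$age, tab$rate_per_100py)
}

#' Synthetic allele-frequency panel
#'
#' A deterministic synthetic stand-in for an external effect-allele
#' frequency panel covering the 31 PHS SNPs (the published reference panel
#' is not redistributed here).
#'
#' @return named numeric vector of effect-allele frequencies.
#' @export
synthetic_snp_freqs <- function() {
  tab <- utils::read.delim(system.file("extdata", "synthetic_snp_freqs.tsv",
                                       package = "polyhaz"), comment.char = "#")
  stats::setNames(tab$freq, tab$snp)
}

#' Read GWAS summary statistics
#'
#' Tab-separated with header `snp, chr, pos, a1, a2, beta, p` (`a1` is the
#' effect allele, `beta` the log odds ratio).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "p")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("summary statistics missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(is.na(tab$p) | tab$p <= 0 | tab$p > 1)) {
    stop("malformed p-values in ", path)
  }
  tab
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF: GT fields are converted to effect-allele dosages with the ALT
#' allele as effect allele (downstream scoring flips dosages when a weight
#' table's effect allele matches REF instead). Dosage TSV: tab-separated,
#' individuals as rows, one column per variant headed `id:EFFECT_ALLELE`
#' (or plain `id`), `.` for missing.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage_tsv"` (guessed from the extension by
#'   default).
#' @return a `phs_genotypes` object (without APOE dosages, which live in
#'   the phenotype file).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- fix$ID
  if (anyDuplicated(ids)) stop("duplicated variant ids in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(a == "1"), numeric(1)))
  }
  dosage <- apply(gt, 2, count_alt)
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = length(ids))
  dosage <- t(dosage)   # individuals x variants
  colnames(dosage) <- ids
  structure(list(dosage = dosage,
                 variants = data.frame(id = ids, chr = fix$CHROM,
                                       pos = as.numeric(fix$POS),
                                       effect_allele = fix$ALT,
                                       other_allele = fix$REF,
                                       stringsAsFactors = FALSE),
                 individuals = rownames(dosage),
                 apoe_e2 = NULL, apoe_e4 = NULL),
            class = "phs_genotypes")
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, na.strings = ".",
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "iid") stop("dosage TSV must start with an `iid` column")
  ids <- tab$iid
  M <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  if (any(M < 0 | M > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  hdr <- colnames(M)
  has_allele <- grepl(":", hdr, fixed = TRUE)
  vid <- sub(":.*$", "", hdr)
  ea <- ifelse(has_allele, sub("^.*:", "", hdr), ".")
  if (anyDuplicated(vid)) stop("duplicated variant ids in ", path)
  colnames(M) <- vid
  rownames(M) <- ids
  structure(list(dosage = M,
                 variants = data.frame(id = vid, effect_allele = ea,
                                       other_allele = ".",
                                       stringsAsFactors = FALSE),
                 individuals = ids, apoe_e2 = NULL, apoe_e4 = NULL),
            class = "phs_genotypes")
}

#' Write genotypes as dosage TSV
#'
#' @param genotypes a `phs_genotypes` object.
#' @param path output path.
#' @export
write_genotypes <- function(genotypes, path) {
  hdr <- ifelse(genotypes$variants$effect_allele %in% c(".", NA),
                genotypes$variants$id,
                paste0(genotypes$variants$id, ":",
                       genotypes$variants$effect_allele))
  M <- genotypes$dosage
  tab <- data.frame(iid = rownames(M), M, check.names = FALSE)
  names(tab) <- c("iid", hdr)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a phenotype/covariate CSV
#'
#' Required columns: `iid`, `sex`, `apoe_e2`, `apoe_e4`, `pc1`..`pc5`,
#' `onset_age` (empty for non-cases), `last_visit_age`; optional
#' `entry_age` (default 60). The event indicator is inferred from onset
#' presence; events with onset below `min_age` are excluded (count
#' reported via message).
#'
#' @param path file path.
#' @param min_age minimum onset age policy (default 60).
#' @return `phs_cohort` data frame with `entry_age`, `exit_age`, `event`.
#' @export
read_phenotypes <- function(path, min_age = 60) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("iid", "sex", "apoe_e2", "apoe_e4", paste0("pc", 1:5),
            "onset_age", "last_visit_age")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("phenotype file missing columns: ",
                         paste(miss, collapse = ", "))
  tab$event <- as.integer(!is.na(tab$onset_age))
  if (!all(tab$event %in% c(0, 1))) stop("event indicator must be 0/1")
  tab$exit_age <- ifelse(tab$event == 1, tab$onset_age, tab$last_visit_age)
  if (!"entry_age" %in% names(tab)) tab$entry_age <- 60
  drop <- tab$event == 1 & tab$onset_age < min_age
  if (any(drop)) {
    message(sum(drop), " records excluded (onset before age ", min_age, ")")
    tab <- tab[!drop, , drop = FALSE]
  }
  bad <- which(tab$exit_age <= tab$entry_age)
  if (length(bad)) stop("exit age <= entry age at rows: ",
                        paste(utils::head(bad, 10), collapse = ", "))
  class(tab) <- c("phs_cohort", "data.frame")
  tab
}

#' Write a phenotype CSV
#'
#' @param cohort a `phs_cohort` data frame.
#' @param path output path.
#' @export
write_phenotypes <- function(cohort, path) {
  cohort <- as.data.frame(cohort)
  cohort$onset_age <- ifelse(cohort$event == 1, cohort$exit_age, NA)
  cohort$last_visit_age <- ifelse(cohort$event == 0, cohort$exit_age,
                                  cohort$exit_age)
  keep <- intersect(c("iid", "sex", "apoe_e2", "apoe_e4", paste0("pc", 1:5),
                      "entry_age", "onset_age", "last_visit_age"),
                    names(cohort))
  utils::write.csv(cohort[, keep], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write PHS weight tables
#'
#' Tab-separated mirror of the weight-table layout: `id`, `beta`, and
#' optionally `se`, `p`, `mlog10p`, `effect_allele`.
#'
#' @param path file path.
#' @return `phs_beta_table`.
#' @export
read_beta_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "beta") %in% names(out))) {
    stop("weight table needs `id` and `beta` columns")
  }
  class(out) <- c("phs_beta_table", "data.frame")
  out
}

#' @rdname read_beta_table
#' @param betas `phs_beta_table` to write.
#' @export
write_beta_table <- function(betas, path) {
  utils::write.table(as.data.frame(betas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a baseline incidence CSV (`age`, `rate_per_100py`)
#'
#' @param path file path.
#' @return `phs_baseline`.
#' @export
read_baseline <- function(path) {
  tab <- utils::read.csv(path)
  baseline_incidence(tab$age, tab$rate_per_100py)
}

#' Run the full PHS pipeline
#'
#' prescreen -> stepwise selection -> bootstrap averaging -> scoring ->
#' reference distribution -> baseline calibration -> incidence table, with
#' an optional held-out validation stage; writes every artifact plus a
#' reproducibility manifest into the output directory.
#'
#' @param config named list (or YAML path via [read_run_config()]):
#'   `paths` (`summary_stats`, `genotypes`, `phenotypes`, `frequencies`,
#'   `baseline`, optional `validation_genotypes`/`validation_phenotypes`),
#'   `params` (`p_threshold`, `tol`, `B`, `n_mc`, `dt`, `direction_filter`,
#'   `ties`), `seed`, `out_dir`.
#' @return invisible list of the main artifacts.
#' @export
run_pipeline <- function(config) {
  p <- config$params %||% list()
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir missing")
  for (f in c("summary_stats", "genotypes", "phenotypes", "frequencies",
              "baseline")) {
    if (is.null(config$paths[[f]])) stop("config error: paths$", f, " missing")
    if (!file.exists(config$paths[[f]])) {
      stop("config error: paths$", f, " does not exist: ", config$paths[[f]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, ...) message("[", stage, "] ", ...)

  stats_tab <- read_summary_stats(config$paths$summary_stats)
  candidates <- prescreen(stats_tab, p_threshold = p$p_threshold %||% 1e-5,
                          direction_filter = isTRUE(p$direction_filter))
  log_msg("prescreen", length(candidates), " candidates of ",
          nrow(stats_tab), " variants")

  geno <- read_genotypes(config$paths$genotypes)
  pheno <- read_phenotypes(config$paths$phenotypes)
  if (!identical(sort(geno$individuals), sort(pheno$iid))) {
    stop("genotype and phenotype individuals do not match")
  }
  geno$dosage <- geno$dosage[match(pheno$iid, geno$individuals), , drop = FALSE]
  cohort <- cbind(as.data.frame(pheno), as.data.frame(geno$dosage))
  base_cov <- c("sex", "apoe_e2", "apoe_e4", paste0("pc", 1:5))
  ties <- p$ties %||% "efron"

  sel <- stepwise_select(cohort, candidates, base_cov,
                         tol = p$tol %||% 3, ties = ties)
  log_msg("stepwise", length(sel$selected), " SNPs selected")
  utils::write.table(sel$trace, file.path(out_dir, "selection_trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  betas <- bootstrap_betas(cohort, sel$selected, base_cov,
                           B = p$B %||% 1000, seed = seed, ties = ties)
  # report APOE rows under the canonical ids used by the weight-table format
  betas$id[betas$id == "apoe_e2"] <- "APOE_e2"
  betas$id[betas$id == "apoe_e4"] <- "APOE_e4"
  write_beta_table(betas, file.path(out_dir, "beta_table.tsv"))
  log_msg("bootstrap", attr(betas, "n_converged"), " converged resamples")

  freq_tab <- utils::read.delim(config$paths$frequencies,
                                comment.char = "#")
  freqs <- stats::setNames(freq_tab$freq, freq_tab$snp)
  dist <- reference_distribution(betas, freqs,
                                 method = "monte_carlo",
                                 n_mc = p$n_mc %||% 2e5, seed = seed)
  scores <- compute_phs(betas, geno, apoe_e2 = pheno$apoe_e2,
                        apoe_e4 = pheno$apoe_e4, freqs = freqs,
                        center = dist)
  utils::write.csv(data.frame(iid = pheno$iid, phs = scores,
                              percentile = percentile_of(scores, dist)),
                   file.path(out_dir, "scores.csv"), row.names = FALSE)

  baseline <- read_baseline(config$paths$baseline)
  cal <- calibrate_baseline(baseline, dist, dt = p$dt %||% 0.25)
  log_msg("calibrate", "reconstruction residual ",
          format(cal$max_residual))
  itab <- incidence_table(cal, apoe_strata = TRUE)
  utils::write.csv(as.data.frame(itab),
                   file.path(out_dir, "incidence_table.csv"),
                   row.names = FALSE)

  validation <- NULL
  if (!is.null(config$paths$validation_phenotypes)) {
    vg <- read_genotypes(config$paths$validation_genotypes)
    vp <- read_phenotypes(config$paths$validation_phenotypes)
    vg$dosage <- vg$dosage[match(vp$iid, vg$individuals), , drop = FALSE]
    vscores <- compute_phs(betas, vg, apoe_e2 = vp$apoe_e2,
                           apoe_e4 = vp$apoe_e4, freqs = freqs,
                           center = dist)
    cases <- vp$event == 1
    oc <- onset_correlation(vp[cases, , drop = FALSE], vscores[cases], cal)
    dh <- decile_hr(vp, vscores)
    validation <- list(onset_r = oc$r, onset_p = oc$p,
                       decile_hr = dh$hr, decile_ci = dh$ci,
                       decile_logrank_p = dh$logrank_p)
    jsonlite::write_json(validation,
                         file.path(out_dir, "validation_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_msg("validate", "onset r = ", round(oc$r, 3),
            ", decile HR = ", round(dh$hr, 2))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("polyhaz")),
    r_version = as.character(getRversion()),
    seed = seed, params = p, paths = config$paths,
    n_candidates = length(candidates), selected = sel$selected,
    n_individuals = nrow(cohort), n_events = sum(cohort$event))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(candidates = candidates, selection = sel, betas = betas,
                 scores = scores, dist = dist, calibration = cal,
                 incidence = itab, validation = validation,
                 manifest = manifest))
}

#' Read a YAML run configuration
#'
#' @param path YAML file with `paths`, `params`, `seed`, `out_dir`.
#' @return config list for [run_pipeline()].
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
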