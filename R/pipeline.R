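PIPELINE_DEFAULTS <- list(
  expr = NA_character_,            # expression TSV
  allele = NA_character_,          # allele-count TSV
  sheet = NA_character_,           # sample sheet TSV
  ann = NA_character_,             # annotation BED
  ann_format = "bed",
  has = NA_character_,             # optional high-affinity-site BED
  enrichment = NA_character_,      # optional per-gene enrichment TSV
  normalization = "reference",     # reference | all_autosomes | total_reads
  rpkm_min = 5,
  paternal_min_fraction = 0.40,
  compensated_cutoff = 1.5,
  n_boot = 1000,
  n_reps = 1000,
  seed = 1,
  neo_is_sex = TRUE,
  quiet = FALSE)

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' rejected before any computation. Values are coerced to the type of the
#' corresponding default.
#'
#' @param path config file path.
#' @return named list merging the file over the documented defaults.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- PIPELINE_DEFAULTS
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(PIPELINE_DEFAULTS)) stop("unknown config key: ", key)
    proto <- PIPELINE_DEFAULTS[[key]]
    cfg[[key]] <- if (is.numeric(proto)) as.numeric(val)
      else if (is.logical(proto)) as.logical(val)
      else val
  }
  cfg
}

pipe_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates validation, normalization, allele-fraction computation,
#' zygotic calls under both definitions, female:male bias tables and class
#' proportions per stage, the maternal-allele onset report
#' (transcript-level zygotic definition, to avoid allele-on-allele
#' circularity), neo-allele partitioning when the annotation carries
#' neo-ORF calls, and (when inputs are provided) the high-affinity-site
#' proximity and H4K16ac comparisons. All stage outputs are written as TSV
#' into `out_dir` together with a manifest; reruns with the same seed are
#' byte-identical.
#'
#' @param config named list (see [read_run_config()]) or a config file
#'   path. Either the four input paths must be set, or `tables` supplied.
#' @param out_dir output directory.
#' @param tables optional pre-loaded inputs: list with `expr`, `allele`,
#'   `sheet`, `ann` (bypasses the path-based readers; used by
#'   simulation-driven runs).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, tables = NULL) {
  if (is.character(config) && length(config) == 1L) config <- read_run_config(config)
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L) stop("unknown config key(s): ",
                                 paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  q <- isTRUE(cfg$quiet)
  set.seed(as.integer(cfg$seed))

  pipe_log(q, "validate", "loading and cross-validating inputs")
  if (is.null(tables)) {
    ann <- read_annotation(cfg$ann, format = cfg$ann_format)
    tabs <- read_tables(cfg$expr, cfg$allele, cfg$sheet, ann = ann)
  } else {
    ann <- tables$ann
    tabs <- validate_tables(tables$expr, tables$allele, tables$sheet, ann = ann)
  }
  expr <- tabs$expr; allele <- tabs$allele; sheet <- tabs$sheet

  pipe_log(q, "preprocess", "autosomal normalization (", cfg$normalization, ")")
  norm <- normalize_autosomal(expr, ann, mode = cfg$normalization,
                              neo_is_sex = cfg$neo_is_sex)
  fractions <- allele_fractions(allele)
  zf <- zygotic_fraction(fractions, sheet, ann, neo_is_sex = cfg$neo_is_sex)
  utils::write.table(zf$by_stage, file.path(out_dir, "zygotic_fraction_by_stage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pipe_log(q, "zygotic", "calling zygotic genes under both definitions")
  calls_as <- call_allele_specific(norm, fractions, sheet,
                                   rpkm_min = cfg$rpkm_min,
                                   paternal_min_fraction = cfg$paternal_min_fraction)
  calls_tl <- call_transcript_level(norm, sheet, rpkm_min = cfg$rpkm_min)
  onset_stage <- first_zygotic_stage(calls_as)
  utils::write.table(
    data.frame(gene_id = names(onset_stage), first_zygotic_stage = onset_stage),
    file.path(out_dir, "first_zygotic_stage.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  pipe_log(q, "bias", "female:male ratios and bias classes per stage")
  bias_all <- do.call(rbind, lapply(sort(unique(sheet$stage)), function(st) {
    suppressWarnings(fm_ratio(norm, sheet, st, zygotic_calls = calls_as,
                              rpkm_min = cfg$rpkm_min))
  }))
  class(bias_all) <- c("bias_table", "data.frame")
  utils::write.table(bias_all[bias_all$included, ],
                     file.path(out_dir, "fm_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  classes <- classify_bias(bias_all, ann)
  utils::write.table(classes, file.path(out_dir, "bias_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pipe_log(q, "compensation", "maternal-allele onset report (n_boot = ", cfg$n_boot, ")")
  onset <- maternal_allele_onset(
    fractions, sheet, ann,
    zygotic_genes = rownames(norm$values)[calls_tl$zygotic],
    n_boot = cfg$n_boot, seed = as.integer(cfg$seed),
    scale_factors = attr(norm, "scale_factors"),
    neo_is_sex = cfg$neo_is_sex)
  utils::write.table(onset$table, file.path(out_dir, "onset_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  neo_partition <- NULL
  if (any(ann$neoY_orf != "not_applicable")) {
    pipe_log(q, "compensation", "neo-X/neo-Y partition and ORF strata")
    neo_partition <- partition_neo_alleles(allele, ann, sheet)
    utils::write.table(neo_partition, file.path(out_dir, "neo_partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    orf <- orf_stratified_bias(bias_all, ann, mode = "combined_neoXY")
    utils::write.table(orf$summary, file.path(out_dir, "orf_strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  labels <- compensation_labels(bias_all, threshold = cfg$compensated_cutoff)
  spatial <- clustering_test(
    labels, ann,
    zygotic_genes = rownames(norm$values)[calls_tl$zygotic],
    null_universe = "zygotic", n_reps = cfg$n_reps, seed = as.integer(cfg$seed))
  if (!is.null(spatial)) {
    utils::write.table(spatial, file.path(out_dir, "spatial_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  has_res <- NULL
  if (!is.na(cfg$has)) {
    pipe_log(q, "spatial", "high-affinity-site proximity test")
    has <- read_annotation(cfg$has, format = "bed")
    has_res <- has_proximity_test(bias_all, data.frame(
      chromosome = has$chromosome, start = has$start, end = has$end), ann)
    utils::write.table(has_res, file.path(out_dir, "has_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  enrich_res <- NULL
  if (!is.na(cfg$enrichment)) {
    pipe_log(q, "chromatin", "H4K16ac comparison")
    e <- utils::read.delim(cfg$enrichment, stringsAsFactors = FALSE)
    enrichment <- stats::setNames(e[[2]], e[[1]])
    enrich_res <- h4k16ac_compare(labels, enrichment, ann,
                                  n_boot = cfg$n_boot, seed = as.integer(cfg$seed))
    utils::write.table(enrich_res, file.path(out_dir, "h4k16ac_compare.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("embryocomp"))),
    sprintf("seed\t%d", as.integer(cfg$seed)),
    sprintf("n_genes\t%d", nrow(norm$values)),
    sprintf("n_samples\t%d", ncol(norm$values)),
    sprintf("n_zygotic_allele_specific\t%d",
            sum(apply(calls_as$calls, 1, function(v) any(!is.na(v) & v)))),
    sprintf("n_zygotic_transcript_level\t%d", sum(calls_tl$zygotic)),
    sprintf("zygotic_definition_bias\tallele_specific"),
    sprintf("zygotic_definition_onset\ttranscript_level"),
    vapply(names(PIPELINE_DEFAULTS), function(k)
      sprintf("config_%s\t%s", k, as.character(cfg[[k]])), character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  pipe_log(q, "report", "wrote outputs to ", out_dir)

  invisible(list(norm = norm, fractions = fractions, zygotic_fraction = zf,
                 calls_allele_specific = calls_as,
                 calls_transcript_level = calls_tl,
                 bias = bias_all, bias_classes = classes, onset = onset,
                 neo_partition = neo_partition, labels = labels,
                 spatial = spatial, has = has_res, enrichment = enrich_res))
}
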