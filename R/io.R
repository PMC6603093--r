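# Readers and writers: bulk depth tables as TSV, two-sample VCF with AD
# fields (read via vcfR, minimal write), QTL intervals as BED, and
# simulation scenario configs.

#' Read / write a bulk depth table as TSV
#'
#' The canonical interchange format: a tab-delimited table with columns
#' `chrom`, `pos`, `<bulkA>.ref`, `<bulkA>.alt`, `<bulkB>.ref`,
#' `<bulkB>.alt` (bulk names are recovered from the header), 1-based
#' positions.  Writing then reading is an identity.
#'
#' @param path File path.
#' @return `read_bulk_tsv()` returns a [bulk_depth_table()];
#'   `write_bulk_tsv()` returns `path` invisibly.
#' @export
read_bulk_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 6 || !identical(names(d)[1:2], c("chrom", "pos")))
    stop("expected 6 columns: chrom, pos, <bulkA>.ref, <bulkA>.alt, <bulkB>.ref, <bulkB>.alt")
  bn <- unique(sub("\\.(ref|alt)$", "", names(d)[3:6]))
  if (length(bn) != 2 ||
      !identical(names(d)[3:6], c(paste0(bn[1], c(".ref", ".alt")),
                                  paste0(bn[2], c(".ref", ".alt")))))
    stop("depth columns must be <bulkA>.ref, <bulkA>.alt, <bulkB>.ref, <bulkB>.alt")
  bulk_depth_table(d$chrom, d$pos, d[[3]], d[[4]], d[[5]], d[[6]],
                   bulk_names = bn)
}

#' @rdname read_bulk_tsv
#' @param table A [bulk_depth_table()].
#' @export
write_bulk_tsv <- function(table, path) {
  stopifnot(inherits(table, "bulk_depth_table"))
  bn <- attr(table, "bulk_names")
  out <- as.data.frame(table)
  names(out) <- c("chrom", "pos", paste0(bn[1], c(".ref", ".alt")),
                  paste0(bn[2], c(".ref", ".alt")))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bulk allele depths from a two-sample VCF
#'
#' Extracts per-sample allele depths (the `AD` FORMAT field) for two bulk
#' samples from a VCF.  Only biallelic SNP records are used; multiallelic
#' records, indels and records with a missing or malformed `AD` in either
#' bulk are skipped, with counts reported in the attached `skip_report`
#' attribute.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples Length-2 character vector of sample names, in bulk
#'   order.
#' @return A [bulk_depth_table()] with attribute `skip_report`.
#' @export
read_bulk_vcf <- function(path, samples) {
  stopifnot(length(samples) == 2)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(v@gt)[-1]
  missing <- setdiff(samples, have)
  if (length(missing))
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
  fix <- vcfR::getFIX(v)
  n_in <- nrow(fix)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  indel <- !multi & (nchar(fix[, "REF"]) != 1 | nchar(fix[, "ALT"]) != 1 |
                       is.na(fix[, "ALT"]))
  keep <- !multi & !indel
  ad <- vcfR::extract.gt(v, element = "AD")
  parse_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    ref <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    alt <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else NA_character_, "")))
    cbind(ref = ref, alt = alt)
  }
  ad1 <- parse_ad(ad[, samples[1]])
  ad2 <- parse_ad(ad[, samples[2]])
  bad_ad <- keep & (is.na(ad1[, 1]) | is.na(ad1[, 2]) |
                      is.na(ad2[, 1]) | is.na(ad2[, 2]))
  keep <- keep & !bad_ad
  tbl <- bulk_depth_table(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                          ad1[keep, 1], ad1[keep, 2],
                          ad2[keep, 1], ad2[keep, 2],
                          bulk_names = samples)
  attr(tbl, "skip_report") <- c(input = n_in, multiallelic = sum(multi),
                                indel = sum(indel), missing_ad = sum(bad_ad),
                                retained = sum(keep))
  tbl
}

#' Write a bulk depth table as a minimal two-sample VCF
#'
#' Emits a minimal VCFv4.2 file with one `AD`-only FORMAT field and the
#' two bulks as samples.  Ref/alt bases are placeholders (`A`/`T`), since
#' the scan consumes only depths.
#'
#' @param table A [bulk_depth_table()].
#' @param path Output file.
#' @export
write_bulk_vcf <- function(table, path) {
  stopifnot(inherits(table, "bulk_depth_table"))
  bn <- attr(table, "bulk_names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=seedqtl",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           bn[1], "\t", bn[2])), con)
  if (nrow(table))
    writeLines(sprintf("%s\t%d\t.\tA\tT\t.\t.\t.\tAD\t%d,%d\t%d,%d",
                       table$chrom, table$pos, table$ref_a, table$alt_a,
                       table$ref_b, table$alt_b), con)
  invisible(path)
}

#' Write QTL intervals as a BED file
#'
#' Converts the scan's 1-based half-open intervals to BED's 0-based
#' half-open convention: BED start = `start - 1`, BED end = `end - 1`
#' (both conventions exclude their end, the shift moves only the origin).
#' The name field records the peak position and alpha.
#'
#' @param intervals A [call_qtl()] result.
#' @param path Output file.
#' @export
write_intervals_bed <- function(intervals, path) {
  stopifnot(inherits(intervals, "qtl_intervals"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# QTL intervals (BED: 0-based half-open); name = peak=<bp>;alpha=<level>",
             con)
  if (nrow(intervals))
    writeLines(sprintf("%s\t%d\t%d\tpeak=%d;alpha=%g\t%.4f",
                       intervals$chrom, intervals$start - 1L,
                       intervals$end - 1L, intervals$peak_pos,
                       intervals$alpha, intervals$peak_stat), con)
  invisible(path)
}

#' Run a simulation scenario from a config
#'
#' A scenario config (YAML file or list) describes a full synthetic
#' QTL-seq design: chromosomes, marker spacing, penetrance model, causal
#' markers, bulk specs, depth and error rate.  Keys: `chromosomes` (list
#' of `chrom`, `length_bp`), `marker_spacing_bp`, `bp_per_cM`,
#' `map_function`, `n`, `model` (path to a [read_penetrance_model()]
#' config, or `"seed_coat"` for the built-in four-gene model),
#' `causal_markers` (map locus -> marker name), `bulks` (list of `label`,
#' `phenotypes`, `size`), `mean_depth`, `error_rate`, `seed`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param seed Optional seed overriding the config's.
#' @return List with `pop` (`f2_pop`), `bulks` and `depths`
#'   ([bulk_depth_table]).
#' @export
run_scenario <- function(config, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  req <- c("chromosomes", "n", "model", "causal_markers", "bulks")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("scenario config lacks: ", paste(miss, collapse = ", "))
  known <- c(req, "marker_spacing_bp", "bp_per_cM", "map_function",
             "mean_depth", "error_rate", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown scenario keys: ", paste(extra, collapse = ", "))
  seed <- seed %||% cfg$seed %||% 1L
  chroms <- setNames(vapply(cfg$chromosomes, `[[`, 0, "length_bp"),
                     vapply(cfg$chromosomes, `[[`, "", "chrom"))
  map <- uniform_map(chroms,
                     spacing_bp = cfg$marker_spacing_bp %||% 1e4,
                     map_function = cfg$map_function %||% "kosambi",
                     bp_per_cM = cfg$bp_per_cM %||% 3e5)
  model <- if (identical(cfg$model, "seed_coat")) seed_coat_model()
           else read_penetrance_model(cfg$model)
  pop <- simulate_f2(map, cfg$n, seed = seed)
  pop <- assign_phenotypes(pop, model, unlist(cfg$causal_markers))
  specs <- lapply(cfg$bulks, function(b)
    bulk_spec(b$label, unlist(b$phenotypes), b$size))
  bulks <- make_bulks(pop, specs)
  depths <- sample_bulk_depths(pop, bulks,
                               mean_depth = cfg$mean_depth %||% 83,
                               error_rate = cfg$error_rate %||% 0.005)
  list(pop = pop, bulks = bulks, depths = depths)
}
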