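#' Write / read a mitogenome as FASTA plus a feature table
#'
#' The sequence goes to FASTA (via Biostrings); the annotation goes to a
#' BED-like tab-separated table with header
#' \code{name, type, start, end, strand, frame} using 1-based inclusive
#' coordinates (unlike true BED, which is 0-based half-open — hence the
#' explicit header).
#'
#' @param genome a \linkS4class{Mitogenome}.
#' @param fastaPath,featurePath output (resp. input) file paths.
#' @param name FASTA record name.
#' @return \code{readMitogenome} returns a \linkS4class{Mitogenome};
#'   \code{writeMitogenome} returns the paths invisibly.
#' @export
writeMitogenome <- function(genome, fastaPath, featurePath, name = "mito") {
  ss <- Biostrings::DNAStringSet(genomeSequence(genome))
  names(ss) <- name
  Biostrings::writeXStringSet(ss, fastaPath)
  ft <- genomeFeatures(genome)
  tab <- data.frame(name = ft$name, type = ft$type,
                    start = GenomicRanges::start(ft),
                    end = GenomicRanges::end(ft),
                    strand = as.character(GenomicRanges::strand(ft)),
                    frame = ft$frame, stringsAsFactors = FALSE)
  write.table(tab, featurePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fastaPath, featurePath))
}

#' @rdname writeMitogenome
#' @export
readMitogenome <- function(fastaPath, featurePath) {
  ss <- Biostrings::readDNAStringSet(fastaPath)
  tab <- read.delim(featurePath, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = "mito",
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  gr$name <- tab$name; gr$type <- tab$type
  gr$frame <- as.integer(tab$frame)
  new("Mitogenome", sequence = ss[[1]], features = gr)
}

#' Write / read a pileup as TSV
#'
#' Columns \code{pos, ref, A, C, G, T, depth}; sample metadata (id, nominal
#' coverage, error rate) is preserved in \code{#key=value} header lines.
#'
#' @param pileup a \linkS4class{Pileup}.
#' @param path file path.
#' @return \code{readPileup} returns a \linkS4class{Pileup};
#'   \code{writePileup} the path, invisibly.
#' @export
writePileup <- function(pileup, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample=%s", pileup@sampleId), con)
  writeLines(sprintf("#coverage=%g", pileup@coverage), con)
  writeLines(sprintf("#error_rate=%g", pileup@errorRate), con)
  tab <- data.frame(pos = seq_len(nrow(pileup@counts)), ref = pileup@ref,
                    pileup@counts, depth = rowSums(pileup@counts))
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePileup
#' @export
readPileup <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  gv <- function(key, default) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (base::length(m)) sub(paste0("^#", key, "="), "", m[1]) else default
  }
  tab <- read.delim(text = lines[!grepl("^#", lines)],
                    stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, DNA_BASES4])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, DNA_BASES4)
  if (!all(rowSums(counts) == tab$depth))
    stop("corrupt pileup: depth does not equal the sum of base counts")
  new("Pileup", counts = counts, ref = tab$ref,
      sampleId = gv("sample", "unknown"),
      coverage = as.numeric(gv("coverage", NA)),
      errorRate = as.numeric(gv("error_rate", 0)))
}

CALL_COLUMNS <- c("position", "ref", "alt", "maf", "depth", "sample")

.validateCalls <- function(tab, path = "<calls>") {
  need <- CALL_COLUMNS
  miss <- setdiff(need, names(tab))
  if (base::length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  bad <- which(!is.finite(tab$maf) | tab$maf <= 0 | tab$maf > 0.5)
  if (base::length(bad))
    stop(sprintf(
      "%s: line %d: MAF %s outside (0, 0.5] (minor-allele convention)",
      path, bad[1] + 1L, format(tab$maf[bad[1]])))
  bad <- which(!is.finite(tab$depth) | tab$depth <= 0)
  if (base::length(bad))
    stop(sprintf("%s: line %d: non-positive depth", path, bad[1] + 1L))
  invisible(tab)
}

#' Write / read heteroplasmy call tables
#'
#' TSV dialect: plain tab-separated table with the package's call columns;
#' write-then-read reproduces the table field for field. VCF dialect: a
#' minimal single-sample VCFv4.2 with the minor-allele frequency in the
#' INFO \code{AF} field and depth in \code{DP}; reading requires the
#' \pkg{vcfR} package. Both directions validate the minor-allele invariant
#' (0 < MAF <= 0.5) and positive depth, reporting the offending line.
#'
#' @param calls a call \code{data.frame}.
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @param contig contig name written to the VCF.
#' @return \code{readCalls} returns the call table; \code{writeCalls} the
#'   path, invisibly.
#' @export
writeCalls <- function(calls, path, dialect = c("tsv", "vcf"),
                       contig = "mito") {
  dialect <- match.arg(dialect)
  if (nrow(calls)) .validateCalls(calls)
  if (dialect == "tsv") {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s>", contig),
                 "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
                 "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(calls)) {
      flt <- if ("filter" %in% names(calls))
        ifelse(calls$filter == "PASS", "PASS", calls$filter) else "PASS"
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tAF=%g;DP=%d",
                         contig, calls$position, calls$ref, calls$alt,
                         flt, calls$maf, as.integer(calls$depth)), con)
    }
  }
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (nrow(tab)) .validateCalls(tab, path)
    return(tab)
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, "AF")
  dp <- vcfR::extract.info(v, "DP")
  tab <- data.frame(position = as.integer(fx$POS), ref = fx$REF,
                    alt = fx$ALT, maf = as.numeric(info),
                    depth = as.integer(dp),
                    sample = "vcf", filter = fx$FILTER,
                    stringsAsFactors = FALSE)
  if (nrow(tab)) .validateCalls(tab, path)
  tab
}

#' Write a simulated population as sample and call TSVs
#'
#' @param pop list from [simulatePopulation()].
#' @param dir output directory (created if missing).
#' @return paths of the two files, invisibly.
#' @export
writePopulation <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, "samples.tsv")
  cp <- file.path(dir, "calls.tsv")
  write.table(pop$samples, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pop$calls, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(samples = sp, calls = cp))
}

#' @rdname writePopulation
#' @param samplesPath,callsPath the two TSV paths.
#' @export
readPopulation <- function(samplesPath, callsPath) {
  samples <- read.delim(samplesPath, stringsAsFactors = FALSE)
  calls <- read.delim(callsPath, stringsAsFactors = FALSE)
  if (!all(calls$sample %in% samples$sample))
    stop("call table references samples absent from the sample table")
  list(samples = samples, calls = calls)
}

.CONFIG_DEFAULTS <- list(
  maf_min = 0.01, cov_min = 1000, alpha = 0.05, pad = 500,
  error_rate = 0.001,
  accuracy_denominator = "called", fpr_denominator = "sites",
  chisq_correct = FALSE, quantile_type = 7, seed = NULL)

#' Load a run configuration
#'
#' Reads a YAML file of pipeline settings, fills defaults (which equal the
#' package's documented defaults for every ambiguous rule), rejects unknown
#' keys, validates values, and returns the effective configuration. An empty
#' file yields all defaults.
#'
#' @param path YAML file path; \code{NULL} returns the defaults.
#' @return named list of settings.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (base::length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  if (!is.numeric(cfg$maf_min) || cfg$maf_min < 0 || cfg$maf_min >= 0.5)
    stop("maf_min must lie in [0, 0.5)")
  if (!is.numeric(cfg$cov_min) || cfg$cov_min < 0)
    stop("cov_min must be non-negative")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(cfg$pad) || cfg$pad < 0)
    stop("pad must be non-negative")
  if (!cfg$accuracy_denominator %in% c("called", "all"))
    stop("accuracy_denominator must be 'called' or 'all'")
  if (!cfg$fpr_denominator %in% c("sites", "calls"))
    stop("fpr_denominator must be 'sites' or 'calls'")
  cfg
}
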