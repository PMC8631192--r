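#' Read genomes from a FASTA file
#'
#' One [GenomeRecord-class] per FASTA record. Sequences are uppercased;
#' characters outside A, C, G, T, N are rejected with an error naming the
#' offending record, as are empty sequences.
#'
#' @param path FASTA file.
#' @param circular logical, recycled over records.
#' @return a list of [GenomeRecord-class] objects, named by id.
#' @export
readGenomeFasta <- function(path, circular = FALSE) {
  stopIfNot(file.exists(path), "FASTA file not found: %s", path)
  # read as BString first so alphabet violations are reported per record
  raw <- Biostrings::readBStringSet(path)
  stopIfNot(length(raw) > 0L, "no FASTA records in %s", path)
  ids <- sub("\\s.*$", "", names(raw))
  circular <- rep(circular, length.out = length(raw))
  recs <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    s <- toupper(as.character(raw[[i]]))
    stopIfNot(nzchar(s), "record '%s' has an empty sequence", ids[i])
    if (grepl("[^ACGTN]", s))
      stop(sprintf("record '%s' contains characters outside {A,C,G,T,N}",
                   ids[i]), call. = FALSE)
    recs[[i]] <- genomeRecord(ids[i], s, circular = circular[i])
  }
  names(recs) <- ids
  recs
}

#' Write genomes to a FASTA file
#'
#' @param records a [GenomeRecord-class] or list of them.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(records, path, width = 70L) {
  if (is(records, "GenomeRecord")) records <- list(records)
  set <- Biostrings::DNAStringSet(lapply(records, genomeSeq))
  names(set) <- vapply(records, genomeId, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a rooted tree from a Newick file
#'
#' @param path Newick file holding a single tree.
#' @param requireBinary reject polytomies (mandatory for reconciliation
#'   input) with an explicit "non-binary" error.
#' @return a `phylo`.
#' @export
readNewickTree <- function(path, requireBinary = FALSE) {
  stopIfNot(file.exists(path), "Newick file not found: %s", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop(sprintf(
                   "Newick parse error in %s: %s", path, conditionMessage(e)),
                   call. = FALSE))
  if (is.null(tr)) stop(sprintf("Newick parse error in %s", path),
                        call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (requireBinary && ape::Ntip(tr) >= 2L &&
      !(ape::is.binary(tr) && ape::is.rooted(tr)))
    stop(sprintf("tree in %s is non-binary (polytomy present)", path),
         call. = FALSE)
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a host/phage tree pair plus tip association table
#'
#' The association table is a headed CSV with columns `phage` and `host`
#' giving, for every phage tip, the host tip it is associated with.
#'
#' @param hostPath,phagePath Newick files (binary, rooted).
#' @param mapPath CSV tip-association table.
#' @return a [TreePair-class].
#' @export
readTreePair <- function(hostPath, phagePath, mapPath) {
  host <- readNewickTree(hostPath, requireBinary = TRUE)
  phage <- readNewickTree(phagePath, requireBinary = TRUE)
  tab <- utils::read.csv(mapPath, stringsAsFactors = FALSE)
  stopIfNot(all(c("phage", "host") %in% names(tab)),
            "tip map CSV needs columns 'phage' and 'host'")
  tm <- stats::setNames(as.character(tab$host), as.character(tab$phage))
  treePair(host, phage, tm)
}

#' Validate (and class) a long-format assay table
#'
#' Assay tables hold OD600 or PFU/ml time series in long format with columns
#' `series_id`, `phage_id`, `host_id`, `replicate`, `time` (minutes),
#' `value`, `treatment` (`"phage+"` or `"phage-"`). Checks: times strictly
#' increasing within each series; values non-negative; every `phage+` series
#' has a `phage-` control under the same host and replicate.
#'
#' @param df a data.frame with the columns above.
#' @return `df` with class `AssayTable` prepended.
#' @export
assayTable <- function(df) {
  need <- c("series_id", "phage_id", "host_id", "replicate", "time",
            "value", "treatment")
  stopIfNot(all(need %in% names(df)), "assay table needs columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  stopIfNot(all(df$value >= 0, na.rm = TRUE), "assay values must be >= 0")
  stopIfNot(all(df$treatment %in% c("phage+", "phage-")),
            "treatment must be 'phage+' or 'phage-'")
  for (sid in unique(df$series_id)) {
    tt <- df$time[df$series_id == sid]
    stopIfNot(all(diff(tt) > 0),
              "times not strictly increasing in series '%s'", sid)
  }
  # growth (OD) assays need a no-phage control; PFU series (one-step
  # curves) do not
  if (is.null(df$measure)) df$measure <- "OD"
  od <- df[df$measure == "OD", , drop = FALSE]
  plus <- unique(od[od$treatment == "phage+", c("host_id", "replicate")])
  minus <- unique(od[od$treatment == "phage-", c("host_id", "replicate")])
  key <- function(x) paste(x$host_id, x$replicate, sep = "\r")
  if (!all(key(plus) %in% key(minus)))
    stop("every phage+ series needs a paired phage- control for the same host and replicate",
         call. = FALSE)
  class(df) <- unique(c("AssayTable", class(df)))
  df
}

#' Read an assay table from CSV
#'
#' @param path CSV file (comma-separated, header row, UTF-8).
#' @return a validated `AssayTable` data.frame; see [assayTable()].
#' @export
readAssayTable <- function(path) {
  stopIfNot(file.exists(path), "assay CSV not found: %s", path)
  assayTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read genome features from a GFF3 file
#'
#' Imports a GFF3 and converts it to the feature `GRanges` layout used by
#' [GenomeRecord-class]: metadata columns `type` (the GFF type) and `label`
#' (the `region_class` attribute when present, else `Name`, else `ID`).
#'
#' @param path GFF3 file.
#' @return a `GRanges` with mcols `type` and `label`.
#' @export
readFeatureGff <- function(path) {
  stopIfNot(file.exists(path), "GFF3 file not found: %s", path)
  g <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(g)
  label <- rep(NA_character_, length(g))
  for (col in c("ID", "Name", "region_class")) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      label[!is.na(v)] <- v[!is.na(v)]
    }
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(g),
    ranges = IRanges::ranges(g),
    strand = GenomicRanges::strand(g),
    type = as.character(mc$type),
    label = label)
  out
}

#' Write genome features to a GFF3 file
#'
#' @param features a `GRanges` with mcols `type` and `label` (the layout of
#'   [genomeFeatures()]).
#' @param path output file.
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
writeFeatureGff <- function(features, path, source = "ProphageKit") {
  g <- features
  mc <- S4Vectors::mcols(g)
  S4Vectors::mcols(g) <- NULL
  S4Vectors::mcols(g)$source <- source
  S4Vectors::mcols(g)$type <- mc$type
  S4Vectors::mcols(g)$Name <- mc$label
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' Tabulate prophage calls
#'
#' Flattens a list of [ProphageCall-class] objects into the CSV-ready report
#' layout (one row per call).
#'
#' @param calls list of [ProphageCall-class].
#' @return data.frame with columns genome_id, attL_start, attL_end,
#'   attR_start, attR_end, length, mismatches.
#' @export
prophageCallTable <- function(calls) {
  if (is(calls, "ProphageCall")) calls <- list(calls)
  do.call(rbind, c(list(data.frame(
    genome_id = character(), attL_start = integer(), attL_end = integer(),
    attR_start = integer(), attR_end = integer(), length = integer(),
    mismatches = integer())),
    lapply(calls, function(x) data.frame(
      genome_id = x@genomeId,
      attL_start = IRanges::start(x@attL), attL_end = IRanges::end(x@attL),
      attR_start = IRanges::start(x@attR), attR_end = IRanges::end(x@attR),
      length = x@length, mismatches = x@mismatches))))
}
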