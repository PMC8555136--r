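#' Alignment container
#'
#' A rectangular taxa-by-sites character matrix tied to an alphabet.  All
#' symbols must be states or mapped ambiguity codes of that alphabet
#' (case-insensitive on input; stored upper-case).
#'
#' @param x character matrix with taxon rownames, or a named list/vector of
#'   equal-length sequence strings.
#' @param alphabet a [phy_alphabet()].
#' @return an object of class `phy_alignment` with elements `seq` (character
#'   matrix) and `alphabet`.
#' @export
phy_alignment <- function(x, alphabet) {
  stopifnot(inherits(alphabet, "phy_alphabet"))
  if (is.list(x) || (is.character(x) && !is.matrix(x))) {
    .stop_if(is.null(names(x)) || any(!nzchar(names(x))),
             "sequences must be named by taxon")
    lens <- vapply(x, nchar, integer(1L))
    .stop_if(length(unique(lens)) != 1L,
             "alignment is not rectangular (lengths ",
             paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(unlist(x, use.names = FALSE), ""))
    rownames(mat) <- names(x)
    x <- mat
  }
  .stop_if(!is.matrix(x) || !is.character(x), "need a character matrix")
  .stop_if(is.null(rownames(x)) || anyDuplicated(rownames(x)) > 0L,
           "rows must carry unique taxon names")
  x[] <- toupper(x)
  known <- c(alphabet$states, names(alphabet$ambig))
  bad <- setdiff(unique(as.vector(x)), known)
  .stop_if(length(bad) > 0L, "symbols not in the ", alphabet$name,
           " alphabet: ", paste(bad, collapse = " "))
  structure(list(seq = x, alphabet = alphabet), class = "phy_alignment")
}

#' @export
print.phy_alignment <- function(x, ...) {
  cat("<phy_alignment>", nrow(x$seq), "taxa x", ncol(x$seq), "sites (",
      x$alphabet$name, ")\n")
  invisible(x)
}

#' @rdname phy_alignment
#' @param aln a `phy_alignment`.
#' @export
aln_taxa <- function(aln) rownames(aln$seq)

#' @rdname phy_alignment
#' @export
aln_nsites <- function(aln) ncol(aln$seq)

## subset rows/columns, preserving class
.aln_subset <- function(aln, taxa = NULL, sites = NULL) {
  m <- aln$seq
  if (!is.null(taxa)) m <- m[taxa, , drop = FALSE]
  if (!is.null(sites)) m <- m[, sites, drop = FALSE]
  phy_alignment(m, aln$alphabet)
}

#' Partition map
#'
#' Ordered gene names with half-open 0-based column intervals `[start, end)`
#' that are disjoint and cover the alignment exactly.  The on-disk dialect
#' (RAxML-style `MODEL, name = start-end`) is 1-based inclusive; conversion
#' happens at the file boundary.
#'
#' @param genes character vector of gene names (unique).
#' @param lengths integer vector of gene lengths (sites per gene).
#' @return a `partition_map` data frame with columns `gene`, `start`, `end`.
#' @export
partition_map <- function(genes, lengths) {
  .stop_if(anyDuplicated(genes) > 0L, "duplicate gene name")
  .stop_if(length(genes) != length(lengths), "genes/lengths length mismatch")
  .stop_if(any(lengths < 1L), "every partition needs end > start")
  end <- cumsum(as.integer(lengths))
  start <- c(0L, end[-length(end)])
  structure(data.frame(gene = as.character(genes), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("partition_map", "data.frame"))
}

.check_partitions <- function(parts, nsites) {
  .stop_if(!inherits(parts, "partition_map"), "not a partition_map")
  .stop_if(parts$end[nrow(parts)] != nsites || parts$start[1L] != 0L ||
             any(parts$start[-1L] != parts$end[-nrow(parts)]),
           "partitions must cover the alignment without gaps or overlap")
  invisible(parts)
}

#' Read / write FASTA
#'
#' Minimal exact readers and writers for the plain FASTA used throughout:
#' header lines start with `>`, sequence lines are concatenated.
#'
#' @param file path.
#' @param alphabet a [phy_alphabet()] the sequences are validated against.
#' @return [read_fasta()] returns a `phy_alignment`.
#' @export
read_fasta <- function(file, alphabet) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  .stop_if(!any(hdr) || !hdr[1L], "not a FASTA file: ", file)
  id <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1L))
  names(seqs) <- names
  phy_alignment(seqs, alphabet)
}

#' @rdname read_fasta
#' @param aln a [phy_alignment()].
#' @param width line-wrap width for sequence lines.
#' @export
write_fasta <- function(aln, file, width = 80L) {
  con <- file(file, "w")
  on.exit(close(con))
  for (tx in aln_taxa(aln)) {
    writeLines(paste0(">", tx), con)
    s <- paste(aln$seq[tx, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}

#' Read / write relaxed PHYLIP
#'
#' Relaxed sequential PHYLIP: a header `ntaxa nsites`, then one
#' whitespace-separated `name sequence` record per taxon (names of any
#' length, no 10-character padding).
#'
#' @param file path.
#' @param alphabet a [phy_alphabet()].
#' @return [read_phylip()] returns a `phy_alignment`.
#' @export
read_phylip <- function(file, alphabet) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hd <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
  .stop_if(length(hd) != 2L, "missing PHYLIP header")
  .stop_if(length(lines) - 1L != hd[1L],
           "expected ", hd[1L], " sequence records, found ", length(lines) - 1L)
  parts <- strsplit(trimws(lines[-1L]), "\\s+")
  seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1L))
  names(seqs) <- vapply(parts, `[[`, character(1L), 1L)
  .stop_if(any(nchar(seqs) != hd[2L]), "sequence length differs from header")
  phy_alignment(seqs, alphabet)
}

#' @rdname read_phylip
#' @param aln a [phy_alignment()].
#' @export
write_phylip <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(aln$seq), ncol(aln$seq)), con)
  for (tx in aln_taxa(aln))
    writeLines(paste(tx, paste(aln$seq[tx, ], collapse = "")), con)
  invisible(file)
}

#' Read / write RAxML-style partition files
#'
#' Lines of the form `MODEL, gene = start-end` with 1-based inclusive
#' coordinates, converted to the package's 0-based half-open intervals.
#' Partitions must appear in order and tile the alignment.
#'
#' @param file path.
#' @param nsites total alignment length the partitions must cover.
#' @return [read_partitions()] returns a [partition_map()].
#' @export
read_partitions <- function(file, nsites) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines,
                  regexec("^([^,]+),\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)$",
                          lines))
  ok <- lengths(m) == 5L
  .stop_if(!all(ok), "unparseable partition line: ", lines[!ok][1L])
  genes <- vapply(m, `[[`, character(1L), 3L)
  start1 <- as.integer(vapply(m, `[[`, character(1L), 4L))
  end1 <- as.integer(vapply(m, `[[`, character(1L), 5L))
  pm <- partition_map(genes, end1 - start1 + 1L)
  .stop_if(any(pm$start + 1L != start1), "partitions must be listed in order")
  attr(pm, "models") <- vapply(m, `[[`, character(1L), 2L)
  .check_partitions(pm, nsites)
  pm
}

#' @rdname read_partitions
#' @param parts a [partition_map()].
#' @param model model label written in the first field of each line.
#' @export
write_partitions <- function(parts, file, model = "AUTO") {
  lines <- sprintf("%s, %s = %d-%d", model, parts$gene, parts$start + 1L,
                   parts$end)
  writeLines(lines, file)
  invisible(file)
}

#' Export per-site log-likelihoods as TSV
#'
#' One row per site, one column per tree, natural-log scale.
#'
#' @param site_ll matrix (trees x sites) with tree rownames.
#' @param file output path.
#' @export
write_site_loglik_tsv <- function(site_ll, file) {
  df <- data.frame(site = seq_len(ncol(site_ll)), t(site_ll))
  .write_tsv(df, file)
}
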