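#' @title File format readers and writers
#' @name icrevo-io
#' @details All coordinates are normalized to 0-based half-open (BED
#'   convention). Parsers validate strictly and report the offending file and
#'   line; they never silently coerce malformed records.
NULL

CATEGORIES <- c("ICR_mat", "ICR_pat", "LCP", "HICP", "intergenic", "other")

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
}

#' Read category-labelled intervals from a BED file
#'
#' Expects BED6 plus a seventh column carrying the sequence category
#' (`ICR_mat`, `ICR_pat`, `LCP`, `HICP`, `intergenic`, `other`); as a
#' fallback the category may be carried as a `name` suffix after the last
#' `|` (e.g. `KvDMR|ICR_mat`). Coordinates are 0-based half-open; a `-`
#' strand means the sequence is reverse-complemented on extraction.
#'
#' @param path BED file (tab- or space-separated, `#` comments allowed).
#' @return data.frame with columns chrom, start, end, name, score, strand,
#'   category.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) stop(sprintf("%s: no records", path))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) < 3L) stop(sprintf("%s:%d: fewer than 3 BED fields", path, i))
    start <- suppressWarnings(as.numeric(f[2])); end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end)) {
      stop(sprintf("%s:%d: non-integer coordinates '%s' '%s'", path, i, f[2], f[3]))
    }
    if (start < 0) stop(sprintf("%s:%d: negative start", path, i))
    if (end <= start) stop(sprintf("%s:%d: end must exceed start", path, i))
    name <- if (length(f) >= 4L) f[4] else sprintf("region_%d", i)
    score <- if (length(f) >= 5L) f[5] else "."
    strand <- if (length(f) >= 6L) f[6] else "+"
    if (!strand %in% c("+", "-", ".")) {
      stop(sprintf("%s:%d: invalid strand '%s'", path, i, strand))
    }
    category <- if (length(f) >= 7L) f[7] else {
      parts <- strsplit(name, "|", fixed = TRUE)[[1L]]
      if (length(parts) > 1L) parts[length(parts)] else "other"
    }
    if (!category %in% CATEGORIES) {
      stop(sprintf("%s:%d: unknown category '%s' (expected one of %s)",
                   path, i, category, paste(CATEGORIES, collapse = ", ")))
    }
    data.frame(chrom = f[1], start = start, end = end, name = name,
               score = score, strand = strand, category = category)
  })
  do.call(rbind, rows)
}

#' Read a rooted tree from a newick file
#'
#' @param path newick file.
#' @return a `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(sprintf("%s: not a valid newick file", path))
  tree
}

#' Write a tree to a newick file
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
}

#' Read region alignments from a MAF file
#'
#' Minimal MAF (multiple alignment format) reader: `a` lines open a block,
#' `s` lines carry `src start size strand srcSize text`. Blocks are stitched
#' per reference region in reference order; the reference is the source of
#' the first `s` line of each block. Source names are taken as
#' `species.chrom` (the part before the first dot is the species).
#'
#' @param path MAF file.
#' @param id,category passed to [region_alignment()].
#' @return a `region_alignment` over the species present (species missing
#'   from a block are gap-filled).
#' @export
read_maf <- function(path, id = NULL, category = "other") {
  lines <- readLines(path)
  blocks <- list(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^a($| )", ln)) {
      if (!is.null(cur) && length(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- list()
    } else if (grepl("^s ", ln)) {
      if (is.null(cur)) stop(sprintf("%s:%d: 's' line outside a block", path, i))
      f <- strsplit(ln, "[ \t]+")[[1L]]
      if (length(f) < 7L) stop(sprintf("%s:%d: malformed 's' line", path, i))
      species <- strsplit(f[2], ".", fixed = TRUE)[[1L]][1L]
      cur[[length(cur) + 1L]] <- list(species = species,
                                      start = as.numeric(f[3]),
                                      text = toupper(f[7]))
    }
  }
  if (!is.null(cur) && length(cur)) blocks[[length(blocks) + 1L]] <- cur
  if (length(blocks) == 0L) stop(sprintf("%s: no alignment blocks", path))
  ref_starts <- vapply(blocks, function(b) b[[1L]]$start, 0)
  blocks <- blocks[order(ref_starts)]
  species <- unique(unlist(lapply(blocks, function(b)
    vapply(b, `[[`, "", "species"))))
  parts <- lapply(blocks, function(b) {
    width <- nchar(b[[1L]]$text)
    if (any(vapply(b, function(s) nchar(s$text), 0L) != width)) {
      stop(sprintf("%s: unequal sequence lengths within a block", path))
    }
    out <- setNames(rep(strrep("-", width), length(species)), species)
    for (s in b) out[s$species] <- s$text
    out
  })
  seqs <- vapply(species, function(sp)
    paste(vapply(parts, `[[`, "", sp), collapse = ""), "")
  if (is.null(id)) id <- sub("\\.maf$", "", basename(path))
  region_alignment(setNames(seqs, species), id = id, category = category)
}

#' Read a probe-level expression table
#'
#' One row per probe set with columns `probe_id, gene_id, chrom, unique,
#' signal_MP, signal_0P, signal_00, detp_MP, detp_0P, detp_00, p_0PvMP,
#' lr_0PvMP, p_00vMP, lr_00vMP, p_00v0P, lr_00v0P`. Lines starting with `#`
#' (provenance headers) are skipped.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("probe_id", "gene_id", "chrom", "unique",
                "signal_MP", "signal_0P", "signal_00",
                "detp_MP", "detp_0P", "detp_00",
                "p_0PvMP", "lr_0PvMP", "p_00vMP", "lr_00vMP", "p_00v0P", "lr_00v0P")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  pcols <- grep("^(detp|p)_", required, value = TRUE)
  for (cc in pcols) {
    if (any(df[[cc]] < 0 | df[[cc]] > 1, na.rm = TRUE)) {
      stop(sprintf("%s: column %s has values outside [0,1]", path, cc))
    }
  }
  df
}

#' Read a gene-to-category annotation table
#'
#' Tab-separated columns `gene_id, category_id, category_name` (header
#' optional; detected from the first line).
#'
#' @param path TSV file.
#' @return data.frame with those three columns.
#' @export
read_go_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene_id", first)
  df <- utils::read.table(path, header = header, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (!header) names(df)[1:3] <- c("gene_id", "category_id", "category_name")
  if (any(!nzchar(df$category_id))) stop(sprintf("%s: empty category id", path))
  df
}

#' Write a data frame as TSV with a provenance header
#'
#' The header lines (prefixed `#`) record the package version, the seed and
#' any parameters needed to reproduce the file.
#'
#' @param df data.frame.
#' @param path output file; refused if it exists unless `overwrite = TRUE`.
#' @param params named list recorded in the header.
#' @param overwrite allow replacing an existing file.
#' @export
write_tsv_provenance <- function(df, path, params = list(), overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop(sprintf("%s exists; set overwrite = TRUE to replace it", path))
  }
  hdr <- c(
    sprintf("# icrevo_version=%s", as.character(utils::packageVersion("icrevo"))),
    vapply(names(params), function(k)
      sprintf("# %s=%s", k, paste(format(params[[k]]), collapse = ",")), "")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_provenance()]
#'
#' @param path file path.
#' @return data.frame with a `"provenance"` attribute holding the header
#'   key=value pairs.
#' @export
read_tsv_provenance <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  prov <- list()
  for (i in hdr) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) prov[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "provenance") <- prov
  df
}

#' Save / load a context model as JSON
#'
#' @param model a `context_model` (or fitted model from an `icr_fit`).
#' @param path JSON file.
#' @export
write_context_model <- function(model, path) {
  stopifnot(inherits(model, "context_model"))
  obj <- list(type = model$type, rates = as.list(model$rates),
              root_comp = as.vector(unclass(model$root_comp)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_context_model
#' @export
read_context_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- structure(array(obj$root_comp, c(4, 4, 4)), class = "trinuc_comp")
  new_context_model(obj$type, unlist(obj$rates), comp)
}

#' Extract category-labelled sequences from a genome
#'
#' @param fasta named character vector (e.g. from [read_fasta()]).
#' @param bed data.frame from [read_bed()].
#' @return named character vector of region sequences (reverse-complemented
#'   for `-` strand records), with a `category` attribute.
#' @export
extract_regions <- function(fasta, bed) {
  seqs <- character(nrow(bed))
  for (i in seq_len(nrow(bed))) {
    chrom <- bed$chrom[i]
    if (is.null(fasta[[chrom]]) || is.na(fasta[chrom])) {
      stop(sprintf("chromosome '%s' not in FASTA", chrom))
    }
    s <- fasta[[chrom]]
    if (bed$end[i] > nchar(s)) {
      stop(sprintf("interval %s:%d-%d exceeds sequence length %d",
                   chrom, bed$start[i], bed$end[i], nchar(s)))
    }
    sub <- substr(s, bed$start[i] + 1L, bed$end[i])
    if (bed$strand[i] == "-") sub <- revcomp(sub)
    seqs[i] <- sub
  }
  names(seqs) <- bed$name
  attr(seqs, "category") <- bed$category
  seqs
}
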