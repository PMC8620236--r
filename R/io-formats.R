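## External representations: MELT-dialect VCF, FASTA, Newick, TSV and Nexus
## genotype matrices. VCF coordinates are 1-based; internal interval
## arithmetic elsewhere is 0-based half-open.

#' Read a MELT-dialect VCF of mobile-element insertion calls
#'
#' Parses a VCF 4.x file as written by MELT-style callers: one record per
#' insertion locus, element length in an INFO key, per-side supporting
#' read-pair counts in two further INFO keys, and a GT field per sample.
#' Support keys absent from a record are treated as 0 support (with a warning)
#' so that the downstream cascade filter removes the record - filtering fails
#' closed.
#'
#' @param path VCF file (plain text or gzipped).
#' @param roster character vector of expected sample IDs; the file's samples
#'   must match this set exactly.
#' @param call_class `"REF_MINUS"` (MELT-Split style) or `"REF_PLUS"`
#'   (MELT-Deletion style).
#' @param len_key,left_key,right_key INFO keys carrying the element length and
#'   the 5'/3' support counts. MELT writes discordant-pair evidence as
#'   `LP`/`RP`; other dialects can remap.
#' @param family_key INFO key naming the TE family; records lacking it fall
#'   back to the ID column, then to `"unknown"`.
#' @return A [insertion_calls()] object.
#' @export
read_melt_vcf <- function(path, roster, call_class = "REF_MINUS",
                          len_key = "SVLEN", left_key = "LP",
                          right_key = "RP", family_key = "MEINFO") {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (length(body) && any(nfield < 10))
    stop("malformed VCF line ", body[which(nfield < 10)[1]],
         ": fewer than 10 tab-separated fields")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  file_samples <- colnames(v@gt)[-1]
  missing_s <- setdiff(roster, file_samples)
  extra_s <- setdiff(file_samples, roster)
  if (length(missing_s))
    stop("roster samples absent from VCF: ", paste(missing_s, collapse = ", "))
  if (length(extra_s))
    stop("VCF samples not in roster: ", paste(extra_s, collapse = ", "))

  info_num <- function(key) {
    x <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
    x
  }
  svlen <- abs(info_num(len_key))
  if (anyNA(svlen)) {
    warning("records without ", len_key, " treated as length 0")
    svlen[is.na(svlen)] <- 0
  }
  lsup <- info_num(left_key)
  rsup <- info_num(right_key)
  if (anyNA(lsup) || anyNA(rsup)) {
    warning("records without ", left_key, "/", right_key,
            " treated as 0 support")
    lsup[is.na(lsup)] <- 0
    rsup[is.na(rsup)] <- 0
  }
  fam <- vcfR::extract.info(v, element = family_key)
  fam <- ifelse(is.na(fam), v@fix[, "ID"], sub(",.*", "", fam))
  fam[is.na(fam) | fam == "."] <- "unknown"

  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = list(NULL, colnames(gt)))
  clean <- gsub("\\|", "/", gt)
  dosage[clean %in% c("0/0", "0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1", "1")] <- 2L
  dosage <- dosage[, roster, drop = FALSE]

  info <- data.frame(chrom = v@fix[, "CHROM"],
                     pos = as.integer(v@fix[, "POS"]),
                     family = fam, svlen = as.numeric(svlen),
                     left_support = as.numeric(lsup),
                     right_support = as.numeric(rsup),
                     filter_pass = v@fix[, "FILTER"] %in% c("PASS", "."),
                     stringsAsFactors = FALSE)
  insertion_calls(info, dosage, call_class = call_class)
}

#' Write insertion calls as a MELT-dialect VCF
#'
#' Inverse of [read_melt_vcf()] on the dialect this package reads.
#'
#' @param calls a [insertion_calls()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_melt_vcf <- function(calls, path) {
  stopifnot(inherits(calls, "te_calls"))
  info <- calls$info
  hdr <- c("##fileformat=VCFv4.2",
           "##source=retropop",
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Inserted element length">',
           '##INFO=<ID=LP,Number=1,Type=Integer,Description="Supporting read pairs, 5-prime side">',
           '##INFO=<ID=RP,Number=1,Type=Integer,Description="Supporting read pairs, 3-prime side">',
           '##INFO=<ID=MEINFO,Number=1,Type=String,Description="TE family">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(calls$geno)), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[calls$geno + 1L],
                   nrow = nrow(calls$geno))
  gt_str[is.na(gt_str)] <- "./."
  rows <- vapply(seq_len(nrow(info)), function(i) {
    paste(c(info$chrom[i], info$pos[i],
            sprintf("%s_%d", info$family[i], i), "N",
            if (calls$call_class == "REF_MINUS") "<INS:ME>" else "<DEL:ME>",
            ".", if (info$filter_pass[i]) "PASS" else "lc",
            sprintf("SVLEN=%d;LP=%d;RP=%d;MEINFO=%s", as.integer(info$svlen[i]),
                    as.integer(info$left_support[i]),
                    as.integer(info$right_support[i]), info$family[i]),
            "GT", gt_str[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences, input order kept.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(ss) == 0)) stop("empty FASTA record in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (any(!nzchar(seqs))) stop("refusing to write empty FASTA record")
  ss <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' @param path Newick file.
#' @param require_rooted error on unrooted trees (downstream irreversible
#'   parsimony needs a root; root on the artificial outgroup first).
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path, require_rooted = TRUE) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (require_rooted && !ape::is.rooted(tr))
    stop("tree in ", path, " is unrooted; root it (e.g. on the outgroup)")
  tr
}

#' Write a tree in Newick format
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a genotype or presence matrix to disk
#'
#' TSV output has loci as rows (metadata columns `chrom`, `pos`, `family`,
#' `svlen`, then one column per individual, missing = `NA`); Nexus output is a
#' `DATATYPE=STANDARD` block with symbols `01` and missing `?`, the format
#' consumed by parsimony programs. A `geno_matrix` written as Nexus is first
#' collapsed to presence (dosage >= 1) without adding an outgroup; pass a
#' [presence_matrix()] (e.g. from [encode_presence()]) to include one.
#'
#' @param x a `geno_matrix` or `presence_matrix`.
#' @param path output file.
#' @param format `"tsv"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!inherits(x, "geno_matrix")) stop("TSV output needs a geno_matrix")
    df <- cbind(x$loci[c("chrom", "pos", "family", "svlen")],
                as.data.frame(x$geno))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  pm <- if (inherits(x, "presence_matrix")) x else
    presence_matrix(ifelse(is.na(x$geno), NA_integer_,
                           as.integer(x$geno >= 1L)))
  sym <- matrix(as.character(pm), nrow = nrow(pm))
  sym[is.na(sym)] <- "?"
  taxa <- colnames(pm)
  pad <- formatC(gsub("[^A-Za-z0-9_.]", "_", taxa), width = max(nchar(taxa)),
                 flag = "-")
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", ncol(pm), nrow(pm)),
             '  FORMAT DATATYPE=STANDARD SYMBOLS="01" MISSING=? GAP=-;',
             "  MATRIX",
             paste0("    ", pad, " ",
                    apply(sym, 2, paste, collapse = "")),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genotype matrix written by [write_matrix()] (TSV) or a Nexus
#' STANDARD presence matrix
#'
#' @param path input file.
#' @param format `"tsv"` or `"nexus"`.
#' @param populations population table (required to rebuild a `geno_matrix`
#'   from TSV; see [genotype_matrix()]).
#' @param outgroup for Nexus input, the name of the artificial outgroup taxon
#'   (optional).
#' @return A `geno_matrix` (TSV) or `presence_matrix` (Nexus).
#' @export
read_matrix <- function(path, format = c("tsv", "nexus"), populations = NULL,
                        outgroup = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    meta <- c("chrom", "pos", "family", "svlen")
    if (is.null(populations))
      populations <- data.frame(sample = setdiff(names(df), meta),
                                species = NA_character_,
                                subspecies = NA_character_)
    return(genotype_matrix(as.matrix(df[setdiff(names(df), meta)]),
                           df[meta], populations))
  }
  lines <- trimws(readLines(path))
  mstart <- grep("^MATRIX$", lines, ignore.case = TRUE)
  if (!length(mstart)) stop("no MATRIX block in ", path)
  mend <- grep("^;", lines)
  mend <- mend[mend > mstart][1]
  rows <- lines[(mstart + 1):(mend - 1)]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, "\\s+")
  taxa <- vapply(parts, `[`, "", 1)
  chars <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  codes <- vapply(strsplit(chars, ""), function(ch) {
    x <- suppressWarnings(as.integer(ch))
    x
  }, integer(nchar(chars[1])))
  if (is.null(dim(codes))) codes <- matrix(codes, ncol = length(taxa))
  colnames(codes) <- taxa
  presence_matrix(codes, outgroup = outgroup)
}
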