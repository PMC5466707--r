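#' Write a population VCF (parents first, then RILs)
#'
#' Emits VCF 4.2 with GT-only FORMAT. REF is the parent-1 allele, ALT the
#' parent-2 allele; the two parent samples come first (`0/0` and `1/1`),
#' then one column per RIL with codes `0/0`, `1/1`, `0/1`, `./.` for
#' P1/P2/HET/MISSING.
#'
#' @param snps SNP table (`chrom`, `pos`, `allele_p1`, `allele_p2`).
#' @param obs integer observation matrix (RILs x SNPs).
#' @param path output file.
#' @param p1_name,p2_name parent sample names.
#' @param chrom_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, obs, path, p1_name = "Zhanggu", p2_name = "A2",
                      chrom_lengths = NULL) {
  stopifnot(ncol(obs) == nrow(snps))
  rils <- rownames(obs)
  header <- c("##fileformat=VCFv4.2",
              "##source=binmapper",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(chrom_lengths)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(chrom_lengths), chrom_lengths))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT",
                              p1_name, p2_name, rils), collapse = "\t"))
  gt_map <- c("./.", "0/0", "1/1", "0/1")  # codes 0..3
  gt <- matrix(gt_map[obs + 1L], nrow = nrow(obs))
  body <- vapply(seq_len(nrow(snps)), function(i) {
    paste(c(snps$chrom[i], snps$pos[i], sprintf("m%05d", i),
            snps$allele_p1[i], snps$allele_p2[i], ".", "PASS", ".", "GT",
            "0/0", "1/1", gt[, i]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-parent population VCF into a SNP table and observations
#'
#' Parses with `vcfR`, orients every record by the two named parent
#' samples, and maps each RIL genotype to P1/P2/HET/MISSING. Multi-allelic
#' records and records where either parent is missing or heterozygous are
#' skipped (counted in the `"skipped"` attribute).
#'
#' @param path VCF file.
#' @param p1_name,p2_name parent sample names (must exist in the VCF).
#' @return list with `snps` (data.frame `chrom`, `pos`, `allele_p1`,
#'   `allele_p2`, `missing_frac` over RILs) and `obs` (integer matrix
#'   RILs x SNPs); attribute `"skipped"` on `snps` counts skipped records.
#' @export
read_vcf <- function(path, p1_name = "Zhanggu", p2_name = "A2") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (!all(c(p1_name, p2_name) %in% colnames(gt))) {
    abort("parent sample(s) %s/%s absent from VCF", p1_name, p2_name)
  }
  ril_names <- setdiff(colnames(gt), c(p1_name, p2_name))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) | is.na(fix[, "ALT"])
  pgt <- function(x) sub("\\|", "/", x)
  p1 <- pgt(gt[, p1_name]); p2 <- pgt(gt[, p2_name])
  hom <- c("0/0", "1/1")
  parent_bad <- is.na(p1) | is.na(p2) | !(p1 %in% hom) | !(p2 %in% hom) |
    p1 == p2
  keep <- !multi & !parent_bad
  alleles <- cbind(fix[, "REF"], fix[, "ALT"])
  idx <- which(keep)
  n <- length(idx)
  obs <- matrix(GT_MISSING, nrow = length(ril_names), ncol = n,
                dimnames = list(ril_names, NULL))
  a1 <- a2 <- character(n)
  for (j in seq_len(n)) {
    i <- idx[j]
    p1_allele <- if (p1[i] == "0/0") 1L else 2L  # column into alleles
    a1[j] <- alleles[i, p1_allele]
    a2[j] <- alleles[i, 3L - p1_allele]
    g <- pgt(gt[i, ril_names])
    code <- rep(GT_MISSING, length(g))
    code[g == hom[p1_allele]] <- GT_P1
    code[g == hom[3L - p1_allele]] <- GT_P2
    code[g %in% c("0/1", "1/0")] <- GT_HET
    obs[, j] <- code
  }
  snps <- data.frame(chrom = fix[idx, "CHROM"],
                     pos = as.numeric(fix[idx, "POS"]),
                     allele_p1 = a1, allele_p2 = a2,
                     missing_frac = colMeans(obs == GT_MISSING),
                     stringsAsFactors = FALSE)
  colnames(obs) <- sprintf("m%05d", seq_len(n))
  attr(snps, "skipped") <- c(multiallelic = sum(multi),
                             parent_uninformative = sum(parent_bad & !multi))
  list(snps = snps, obs = obs)
}

#' Read/write FASTA preserving case
#'
#' Thin wrappers over `seqinr`; case is preserved, which matters because
#' gap-filled bases are lowercased.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @param width line width (default 60).
#' @return `read_fasta`: named character vector; `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(vapply(x, function(s) as.character(s)[1L], character(1L)),
                  names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = width)
  invisible(path)
}

#' Write/read a genotype track or bin genotype matrix as TSV
#'
#' Rows are RILs (tracks) or bins (bin matrices), columns the other axis,
#' entries the symbols `a`/`b`/`h`/`-`.
#'
#' @param mat character matrix.
#' @param path file path.
#' @return `read_geno_tsv`: character matrix; writer returns `path`.
#' @export
write_geno_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write bins as BED plus the bin genotype matrix
#'
#' BED is 0-based half-open: `chrom`, `start`, `end`, `bin_id`.
#'
#' @param bin_map a `bin_map`.
#' @param bed_path,geno_path output paths.
#' @return invisibly, the two paths.
#' @export
write_bins <- function(bin_map, bed_path, geno_path) {
  bed <- bin_map$bins[, c("chrom", "start", "end", "bin_id")]
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_geno_tsv(bin_map$geno, geno_path)
  invisible(c(bed_path, geno_path))
}

#' Write simple TSV tables (breakpoints, linkage map, phenotypes, ...)
#'
#' @param df data.frame.
#' @param path file path.
#' @return `path`, invisibly; `read_tsv` returns the data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write an AGP 2.1 file
#'
#' @param agp data.frame from [agp_from_anchors()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  rows <- apply(agp, 1L, function(r) {
    if (r[["component_type"]] == "U") {
      paste(c(r[["object"]], r[["object_beg"]], r[["object_end"]],
              r[["part_number"]], "U", r[["component_beg"]],
              "scaffold", "yes", "map"), collapse = "\t")
    } else {
      paste(c(r[["object"]], r[["object_beg"]], r[["object_end"]],
              r[["part_number"]], "W", r[["component_id"]],
              r[["component_beg"]], r[["component_end"]],
              r[["orientation"]]), collapse = "\t")
    }
  })
  writeLines(rows, con)
  invisible(path)
}
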