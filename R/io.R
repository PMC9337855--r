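# tabular I/O: UTF-8, comma- or tab-delimited by extension, NA token "NA";
# writers prepend a "#" header recording package version and seed

output_header <- function(seed = NULL, config_hash = NULL) {
  v <- as.character(utils::packageVersion("thermogrowth"))
  paste0("# thermogrowth ", v,
         if (!is.null(seed)) paste0(" seed=", seed) else "",
         if (!is.null(config_hash)) paste0(" config=", config_hash) else "")
}

delim_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read and write pipeline tables
#'
#' Thin readers/writers for the pipeline's plain-text tables (phenotypes,
#' climate, accession tables, genotype matrices). Delimiter follows the file
#' extension (`.csv` comma, otherwise tab); `#` lines are metadata comments;
#' missing values are written as `NA`.
#'
#' @param path file path.
#' @param data a data frame.
#' @param seed,config_hash optional metadata recorded in the header comment.
#' @return readers return a tibble (genotypes: a 0/1 matrix with accession
#'   rownames); writers return `path` invisibly.
#' @name thermogrowth-io
NULL

#' @rdname thermogrowth-io
#' @export
read_table_auto <- function(path) {
  readr::read_delim(path, delim = delim_for(path), comment = "#",
                    na = "NA", show_col_types = FALSE)
}

#' @rdname thermogrowth-io
#' @export
write_table_auto <- function(data, path, seed = NULL, config_hash = NULL) {
  readr::write_lines(output_header(seed, config_hash), path)
  if (delim_for(path) == ",") {
    readr::write_csv(data, path, append = TRUE, col_names = TRUE, na = "NA")
  } else {
    readr::write_tsv(data, path, append = TRUE, col_names = TRUE, na = "NA")
  }
  invisible(path)
}

#' @rdname thermogrowth-io
#' @export
read_phenotypes <- function(path) {
  d <- read_table_auto(path)
  require_columns(d, c("plant_id", "accession", "time_dap", "area"),
                  "phenotype table")
  d
}

#' @rdname thermogrowth-io
#' @export
read_genotypes <- function(path) {
  d <- read_table_auto(path)
  require_columns(d, "accession", "genotype table")
  G <- as.matrix(d[, setdiff(names(d), "accession")])
  mode(G) <- "numeric"
  rownames(G) <- d$accession
  G
}

#' @rdname thermogrowth-io
#' @export
write_genotypes <- function(data, path, seed = NULL, config_hash = NULL) {
  df <- tibble::as_tibble(as.data.frame(data), rownames = "accession")
  write_table_auto(df, path, seed, config_hash)
}

#' Read haploid/homozygous genotypes from a VCF file
#'
#' Parses the GT field of a VCF into a 0/1 accession x SNP matrix suitable
#' for inbred panels: haploid calls (`0`/`1`) are used as-is, homozygous
#' diploid calls (`0/0`, `1|1`) are collapsed to a single allele, and
#' heterozygous or missing calls become `NA`.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return a 0/1 matrix (accessions x SNPs) with a `map` attribute
#'   (tibble: `id`, `chr`, `pos`).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    rlang::abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  first <- substr(gt, 1, 1)
  second <- ifelse(nchar(gt) >= 3, substr(gt, 3, 3), first)
  g <- ifelse(first %in% c("0", "1") & first == second,
              as.numeric(first), NA_real_)
  G <- t(matrix(g, nrow = nrow(gt), dimnames = dimnames(gt)))
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"])
  colnames(G) <- ids
  attr(G, "map") <- tibble::tibble(id = ids, chr = fix[, "CHROM"],
                                   pos = as.integer(fix[, "POS"]))
  G
}

#' Write a minimal haploid VCF for an inbred genotype matrix
#'
#' @param G 0/1 accession x SNP matrix; SNP names of the form `chr<k>_<pos>`
#'   are used for coordinates (otherwise sequential positions on chr1).
#' @param path output path.
#' @param map optional tibble (`id`, `chr`, `pos`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path, map = NULL) {
  ids <- colnames(G) %||% sprintf("snp%d", seq_len(ncol(G)))
  if (is.null(map)) {
    m <- regmatches(ids, regexec("^chr([0-9]+)_([0-9]+)$", ids))
    ok <- lengths(m) == 3
    chr <- ifelse(ok, vapply(m, function(x) x[2] %||% NA_character_, ""), "1")
    pos <- ifelse(ok, as.integer(vapply(m, function(x) x[3] %||% NA_character_, "")),
                  seq_len(ncol(G)))
  } else {
    chr <- map$chr[match(ids, map$id)]
    pos <- map$pos[match(ids, map$id)]
  }
  gt <- apply(G, 2, function(x) ifelse(is.na(x), ".", as.character(x)))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(ncol(G)), function(j) {
    paste(c(chr[j], pos[j], ids[j], "A", "T", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
  invisible(path)
}
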