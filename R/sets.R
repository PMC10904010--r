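# SNP-set definitions: non-overlapping 1-Mbp genomic windows and user-named
# (e.g. gene-ontology-derived) sets.

new_snp_set <- function(set_id, snp_ids, provenance) {
  if (length(snp_ids) == 0) stopf("SNP set '%s' is empty", set_id)
  structure(list(set_id = set_id, snp_ids = snp_ids, provenance = provenance),
            class = "sv_snp_set")
}

#' @export
print.sv_snp_set <- function(x, ...) {
  cat(sprintf("<sv_snp_set> %s (%s): %d SNPs\n", x$set_id, x$provenance,
              length(x$snp_ids)))
  invisible(x)
}

#' Partition SNPs into non-overlapping genomic windows
#'
#' Window index on a chromosome is `floor(pos / window_bp) + 1`, so window 1
#' covers positions 1..window_bp-1 and window k >= 2 covers
#' `(k-1)*window_bp .. k*window_bp - 1`. Only non-empty windows are emitted,
#' named `Chr{c}_{k}`.
#'
#' @param snps SNP metadata `data.frame` with `id`, `chrom`, `pos` columns
#'   (e.g. the `snps` element of an [sv_genotypes]).
#' @param window_bp window length in base pairs (default 1 Mbp).
#' @return List of `sv_snp_set` objects ordered by (chromosome, window);
#'   members within a set are ordered by position.
#' @export
partition_genome <- function(snps, window_bp = 1e6) {
  if (nrow(snps) == 0) return(list())
  if (any(snps$pos < 1)) stopf("positions must be 1-based (>= 1)")
  k <- floor(snps$pos / window_bp) + 1
  key <- paste0("Chr", snps$chrom, "_", k)
  ord <- order(snps$chrom, k, snps$pos, snps$id)
  sets <- split(snps$id[ord], factor(key[ord], levels = unique(key[ord])))
  lapply(names(sets), function(nm) new_snp_set(nm, sets[[nm]], "window"))
}

#' Define a named SNP set
#'
#' Builds a user-named set from an explicit id vector or a gene-to-SNP
#' mapping (`data.frame` with `gene` and `snp_id` columns, or a named list of
#' id vectors). Members may span chromosomes. Duplicates are removed keeping
#' the first occurrence; ids absent from `gm` are dropped and reported via
#' the `missing_ids` attribute.
#'
#' @param name set identifier.
#' @param members character vector of SNP ids, or a gene-to-SNP mapping.
#' @param gm optional [sv_genotypes] against which membership is resolved.
#' @return An `sv_snp_set` with provenance `"named"`.
#' @export
define_named_set <- function(name, members, gm = NULL) {
  if (is.data.frame(members)) {
    if (!all(c("gene", "snp_id") %in% names(members)))
      stopf("mapping data.frame needs 'gene' and 'snp_id' columns")
    ids <- as.character(members$snp_id)
  } else if (is.list(members)) {
    ids <- as.character(unlist(members, use.names = FALSE))
  } else {
    ids <- as.character(members)
  }
  ids <- ids[!duplicated(ids)]
  missing_ids <- character(0)
  if (!is.null(gm)) {
    known <- ids %in% gm$snps$id
    missing_ids <- ids[!known]
    ids <- ids[known]
    if (length(ids) == 0)
      stopf("named set '%s': no member found in the genotype matrix (unknown: %s)",
            name, paste(missing_ids, collapse = ", "))
  }
  s <- new_snp_set(name, ids, "named")
  attr(s, "missing_ids") <- missing_ids
  s
}

#' Read / write SNP-set files
#'
#' Two-column TSV `set_name snp_id` with a header line; window partitions can
#' be written in the same format for inspection.
#'
#' @param path file path.
#' @return `read_snp_sets()`: list of `sv_snp_set` (provenance `"named"`).
#' @export
read_snp_sets <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("set_name", "snp_id") %in% names(tab)))
    stopf("%s: expected columns 'set_name' and 'snp_id'", path)
  by_set <- split(tab$snp_id, factor(tab$set_name, levels = unique(tab$set_name)))
  lapply(names(by_set), function(nm) define_named_set(nm, by_set[[nm]]))
}

#' @rdname read_snp_sets
#' @param sets list of `sv_snp_set` objects.
#' @export
write_snp_sets <- function(sets, path) {
  tab <- do.call(rbind, lapply(sets, function(s)
    data.frame(set_name = s$set_id, snp_id = s$snp_ids)))
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
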