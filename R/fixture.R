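#' Load the printed miRNA host-exon table
#'
#' Returns the 23-row miRNA host-exon annotation table shipped with the
#' package: for each exon that hosts (or flanks) a validated miRNA and passed
#' the FDR 0.1 filter, the normalized counts of the two alcohol-exposed and two
#' control pooled samples, the BH-adjusted p-value, and the exon- and
#' gene-level log2 fold changes (control over alcohol). One exon
#' (gga-mir-3064, exon E001) is a high-abundance outlier that downstream
#' PCA/k-means analyses exclude; the fixture keeps it, exclusion is the
#' caller's choice (see [mirna_feature_matrix()]).
#'
#' @return A data.frame with columns `ensembl_exon_id`, `mirbase_id`,
#'   `gene_symbol`, `gene_name`, `alc1`, `alc2`, `cont1`, `cont2`, `bh_p`,
#'   `exon_log2fc`, `gene_log2fc`.
#' @export
load_mirna_fixture <- function() {
  path <- system.file("extdata", "mirna_exons_table.tsv", package = "exonml",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .mirna_fixture_md5))
    stop("miRNA fixture integrity check failed (md5 ", md5, ")", call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(x) == 23L, !anyDuplicated(x$ensembl_exon_id),
            all(x$bh_p < 0.1))
  x
}

# frozen checksum of inst/extdata/mirna_exons_table.tsv
.mirna_fixture_md5 <- "78853e002a6809911fa587069d0c8722"

#' The high-abundance outlier exon excluded from miRNA clustering
#' @return Its `ensembl_exon_id`.
#' @export
mirna_outlier_id <- function() "ENSGALG00000003532+ENSGALG00000027517:E001"

#' Build the miRNA exon feature matrix
#'
#' Assembles the observations-by-variables matrix used for the miRNA PCA,
#' k-means, fuzzy c-means, Hopkins and VAT analyses: the four normalized count
#' columns plus the exon- and gene-level log2 fold changes (6 variables). With
#' the outlier dropped this is the 22 x 6 clustering matrix.
#'
#' @param fixture Fixture table from [load_mirna_fixture()].
#' @param drop_outlier Drop the gga-mir-3064 E001 outlier exon (default TRUE).
#' @param scale Standardize columns to zero mean / unit variance.
#' @return A [feature_matrix()] with rownames `<mirbase_id> <exon>`.
#' @export
mirna_feature_matrix <- function(fixture = load_mirna_fixture(),
                                 drop_outlier = TRUE, scale = FALSE) {
  d <- fixture
  if (drop_outlier) d <- d[d$ensembl_exon_id != mirna_outlier_id(), , drop = FALSE]
  x <- as.matrix(d[, c("alc1", "alc2", "cont1", "cont2",
                       "exon_log2fc", "gene_log2fc")])
  rownames(x) <- paste(d$mirbase_id, sub(".*:", "", d$ensembl_exon_id))
  fm <- feature_matrix(x)
  if (scale) fm <- scale_features(fm)
  fm
}
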