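# Rare-variant filter cascade for annotated exome variant tables: a minor
# allele frequency clause (looser for genes already linked to limb-girdle
# muscular dystrophy), a predicted-pathogenicity clause (at least one damaging
# verdict among the configured predictors), a dbscSNV splice-alteration flag,
# and a transparent deterministic ranking. ACMG codes pass through as labels.

DEFAULT_PREDICTORS <- c("mutation_taster", "polyphen2", "provean", "sift")

DAMAGING_TOKENS <- c("damaging", "probably damaging", "possibly damaging",
                     "deleterious", "disease causing", "disease_causing", "d")
BENIGN_TOKENS <- c("benign", "tolerated", "neutral", "polymorphism", "n", "t")

#' Normalise a predictor verdict string to damaging / benign / absent.
#' @noRd
verdict_of <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("absent", length(x))
  out[x %in% DAMAGING_TOKENS] <- "damaging"
  out[x %in% BENIGN_TOKENS] <- "benign"
  out
}

#' Read an annotated variant table (TSV)
#'
#' Expected columns: `gene`, `cdna`, `protein`, `type`, `maf` (minor allele
#' frequency, blank/NA when the variant is absent from the population
#' database), one column per predictor (verdict strings), `ada_score`,
#' `rf_score` (dbscSNV, blank when not a splice-region variant), `acmg`
#' (semicolon-separated evidence codes) and optionally `location`.
#' Lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return data.frame of class `variant_table`.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("gene", "cdna", "protein", "type", "maf")
  if (!all(need %in% names(df)))
    stop("variant table must have columns ", paste(need, collapse = ", "))
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Filter variants by allele frequency and predicted pathogenicity
#'
#' A record is retained iff (i) its minor allele frequency is absent or below
#' `maf_panel` (3 percent) when the gene is in the disease gene panel, below
#' `maf_other` (1 percent) otherwise, and (ii) at least one configured
#' predictor calls it damaging. Records with malformed frequencies are skipped
#' with an audit note rather than aborting the cascade.
#'
#' @param records a `variant_table` (see [read_variants()]).
#' @param gene_panel character vector of panel gene symbols (e.g. known
#'   limb-girdle muscular dystrophy genes); must be nonempty.
#' @param maf_panel,maf_other frequency thresholds (strict `<`).
#' @param predictors predictor column names; default Mutation Taster,
#'   PolyPhen2, PROVEAN and SIFT.
#' @return list with `retained` (filtered `variant_table`) and `audit`
#'   (data.frame: one row per input record with `retained` and
#'   `failed_clause` in {"", "frequency", "pathogenicity", "malformed_maf"}).
#' @export
filter_variants <- function(records, gene_panel,
                            maf_panel = 0.03, maf_other = 0.01,
                            predictors = DEFAULT_PREDICTORS) {
  if (!length(gene_panel)) stop("gene_panel must be nonempty")
  preds <- intersect(predictors, names(records))
  if (!length(preds)) stop("none of the predictor columns are present")
  n <- nrow(records)
  failed <- character(n)
  for (i in seq_len(n)) {
    maf <- suppressWarnings(as.numeric(records$maf[i]))
    if (!is.na(records$maf[i]) && (is.na(maf) || maf < 0 || maf > 1)) {
      failed[i] <- "malformed_maf"
      next
    }
    thr <- if (records$gene[i] %in% gene_panel) maf_panel else maf_other
    if (!is.na(maf) && maf >= thr) {
      failed[i] <- "frequency"
      next
    }
    verdicts <- vapply(preds, function(p) verdict_of(records[[p]][i]), character(1))
    if (!any(verdicts == "damaging")) failed[i] <- "pathogenicity"
  }
  audit <- data.frame(gene = records$gene, cdna = records$cdna,
                      retained = failed == "", failed_clause = failed,
                      stringsAsFactors = FALSE)
  retained <- records[failed == "", , drop = FALSE]
  class(retained) <- class(records)
  list(retained = retained, audit = audit)
}

#' dbscSNV splice-alteration flag
#'
#' TRUE iff both the adaptive-boosting and the random-forest scores are
#' present and strictly greater than 0.6.
#'
#' @param ada_score,rf_score dbscSNV scores in [0, 1] (NA when absent).
#' @return logical vector.
#' @export
splice_flag <- function(ada_score, rf_score) {
  ada <- suppressWarnings(as.numeric(ada_score))
  rf <- suppressWarnings(as.numeric(rf_score))
  !is.na(ada) & !is.na(rf) & ada > 0.6 & rf > 0.6
}

#' Deterministic variant prioritisation
#'
#' Orders retained variants by a transparent key: truncating variants
#' (nonsense/frameshift) first, then splice-flagged records, then missense by
#' decreasing number of damaging predictor verdicts; ties resolve by gene
#' symbol and then genomic location/cDNA string.
#'
#' @param retained a `variant_table`.
#' @param predictors predictor columns to count (default set).
#' @return the reordered `variant_table` with a `rank` column.
#' @export
rank_variants <- function(retained, predictors = DEFAULT_PREDICTORS) {
  if (!nrow(retained)) {
    retained$rank <- integer(0)
    return(retained)
  }
  preds <- intersect(predictors, names(retained))
  type <- tolower(retained$type)
  truncating <- grepl("nonsense|frameshift|stop", type)
  spl <- if (all(c("ada_score", "rf_score") %in% names(retained)))
    splice_flag(retained$ada_score, retained$rf_score) else rep(FALSE, nrow(retained))
  ndam <- vapply(seq_len(nrow(retained)), function(i)
    sum(vapply(preds, function(p) verdict_of(retained[[p]][i]) == "damaging",
               logical(1))), numeric(1))
  loc <- if ("location" %in% names(retained)) retained$location else retained$cdna
  ord <- order(!truncating, !spl, -ndam, retained$gene, loc)
  out <- retained[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
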