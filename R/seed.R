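# Seed-match scanning of a 3'UTR and seed-class enrichment of interaction
# scores.

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

normalize_rna <- function(seq, what = "sequence") {
  s <- toupper(gsub("\\s", "", seq))
  s <- chartr("T", "U", s)
  if (nchar(s) == 0L) stop(what, " is empty")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% names(RNA_COMPLEMENT))) {
    stop(what, " contains invalid characters (allowed: A, C, G, U/T, N)")
  }
  s
}

reverse_complement_rna <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(rev(unname(RNA_COMPLEMENT[chars])), collapse = "")
}

#' Find miRNA seed-match sites in a 3'UTR
#'
#' Scans the UTR (5'->3', given strand only) for canonical seed-match sites of
#' one mature miRNA:
#' * **6mer** — UTR matches the reverse complement of miRNA nucleotides 2-7;
#' * **7mer** — either the reverse complement of nucleotides 2-8 (7mer-m8) or
#'   a 2-7 match with an A opposite miRNA nucleotide 1 (7mer-A1);
#' * **8mer** — a 2-8 match with the A opposite nucleotide 1.
#'
#' Each genomic site is reported once with its longest applicable type;
#' overlapping sites are allowed. `T` is normalized to `U` and matching is
#' case-insensitive.
#'
#' @param utr 3'UTR sequence (character scalar, RNA or DNA alphabet).
#' @param mirna Mature miRNA sequence, at least 8 nt.
#' @param mirna_id Optional identifier recorded in the output.
#' @return Data frame with columns `mirna_id`, `utr_start` (1-based position
#'   of the site's 5' end), `site_type` (`"6mer"`, `"7mer"`, `"8mer"`),
#'   `site_subtype` (`"6mer"`, `"7mer-m8"`, `"7mer-A1"`, `"8mer"`) and
#'   `site_sequence` (the UTR substring at the reported coordinates).
#' @examples
#' find_seed_matches("GGCUACCUCAGG", "UGAGGUAGUAGGUUGUAUAGUU", "let-7a-5p")
#' @export
find_seed_matches <- function(utr, mirna, mirna_id = "miRNA") {
  utr <- normalize_rna(utr, "UTR")
  mirna <- normalize_rna(mirna, "miRNA")
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt long")

  core6 <- reverse_complement_rna(substr(mirna, 2L, 7L)) # opposite nt 7..2
  m8_comp <- unname(RNA_COMPLEMENT[substr(mirna, 8L, 8L)]) # opposite nt 8, 5' of core
  n <- nchar(utr)
  if (n < 6L) {
    return(empty_site_table())
  }
  starts <- seq_len(n - 5L)
  cores <- substring(utr, starts, starts + 5L)
  hit_pos <- starts[cores == core6]
  if (length(hit_pos) == 0L) {
    return(empty_site_table())
  }
  has_m8 <- hit_pos > 1L & substring(utr, hit_pos - 1L, hit_pos - 1L) == m8_comp
  has_a1 <- hit_pos + 6L <= n & substring(utr, hit_pos + 6L, hit_pos + 6L) == "A"
  subtype <- ifelse(has_m8 & has_a1, "8mer",
             ifelse(has_m8, "7mer-m8",
             ifelse(has_a1, "7mer-A1", "6mer")))
  site_start <- ifelse(has_m8, hit_pos - 1L, hit_pos)
  site_end <- ifelse(has_a1, hit_pos + 6L, hit_pos + 5L)
  data.frame(
    mirna_id = mirna_id,
    utr_start = as.integer(site_start),
    site_type = sub("-.*", "", sub("7mer-(m8|A1)", "7mer", subtype)),
    site_subtype = subtype,
    site_sequence = substring(utr, site_start, site_end),
    stringsAsFactors = FALSE
  )
}

empty_site_table <- function() {
  data.frame(
    mirna_id = character(), utr_start = integer(), site_type = character(),
    site_subtype = character(), site_sequence = character(),
    stringsAsFactors = FALSE
  )
}

#' Best (longest) seed class per miRNA
#'
#' @param utr 3'UTR sequence.
#' @param mirnas Named character vector of mature miRNA sequences.
#' @return Data frame `mirna_id`, `seed_class` (`"none"`, `"6mer"`, `"7mer"`,
#'   `"8mer"`), `n_sites`.
#' @export
classify_seed_sites <- function(utr, mirnas) {
  if (is.null(names(mirnas))) stop("`mirnas` must be named by miRNA id")
  lev <- c("none", "6mer", "7mer", "8mer")
  res <- lapply(names(mirnas), function(id) {
    sites <- find_seed_matches(utr, mirnas[[id]], id)
    cls <- if (nrow(sites) == 0L) "none" else lev[max(match(sites$site_type, lev))]
    data.frame(mirna_id = id, seed_class = cls, n_sites = nrow(sites),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Seed-class enrichment of interaction scores
#'
#' Groups miRNAs by their best seed class in the UTR and compares the
#' interaction-score distribution of each class (6mer, 7mer, 8mer) against
#' miRNAs with no seed-match site, using the two-sample Kolmogorov-Smirnov
#' test. A real repression signal shifts the seed-class distributions towards
#' more negative scores.
#'
#' @param score_table Data frame with `mirna_id` and `score_avg` columns.
#' @param seed_classes Data frame with `mirna_id` and `seed_class` columns
#'   (from [classify_seed_sites()]).
#' @return A list with `tests` (data frame: `seed_class`, `n`, `n_reference`,
#'   `D`, `p_value`, `testable`) and `ecdf` (long data frame of per-class
#'   cumulative distributions: `seed_class`, `score`, `ecdf`).
#' @export
seed_class_enrichment <- function(score_table, seed_classes) {
  merged <- merge(score_table[, c("mirna_id", "score_avg")], seed_classes,
                  by = "mirna_id")
  merged <- merged[is.finite(merged$score_avg), ]
  ref <- merged$score_avg[merged$seed_class == "none"]
  classes <- c("6mer", "7mer", "8mer")
  tests <- lapply(classes, function(cl) {
    x <- merged$score_avg[merged$seed_class == cl]
    testable <- length(x) >= 2L && length(ref) >= 2L
    if (testable) {
      ks <- ks_two_sample(x, ref)
      data.frame(seed_class = cl, n = length(x), n_reference = length(ref),
                 D = ks$statistic, p_value = ks$p_value, testable = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(seed_class = cl, n = length(x), n_reference = length(ref),
                 D = NA_real_, p_value = NA_real_, testable = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  ecdf_tab <- do.call(rbind, lapply(c("none", classes), function(cl) {
    x <- sort(merged$score_avg[merged$seed_class == cl])
    if (length(x) == 0L) return(NULL)
    data.frame(seed_class = cl, score = x,
               ecdf = seq_along(x) / length(x), stringsAsFactors = FALSE)
  }))
  list(tests = do.call(rbind, tests), ecdf = ecdf_tab)
}
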