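#' Enumerate candidate (drug1, drug2, AE) triples
#'
#' Every report listing two or more drugs contributes all of its unordered
#' drug pairs crossed with all of its adverse-event terms. The pair is stored
#' in canonical order (`drug1 < drug2` lexicographically, C collation) so each
#' unordered pair appears once. `n111` counts reports carrying both drugs and
#' the AE; candidates below `min_n111` are dropped.
#'
#' @param reports an [srs_reports] object (filtered and standardized).
#' @param min_n111 minimum co-report count (inclusive). The conventional
#'   screening value is 3; use 1 to enumerate everything.
#' @return A data.frame with columns `drug1`, `drug2`, `ae`, `n111`, sorted
#'   by decreasing `n111`, then `drug1`, `drug2`, `ae`.
#' @export
enumerate_candidates <- function(reports, min_n111 = 3L) {
  stopifnot(inherits(reports, "srs_reports"), min_n111 >= 1L)
  multi <- which(lengths(reports$drugs) >= 2L & lengths(reports$aes) >= 1L)
  empty <- data.frame(drug1 = character(0), drug2 = character(0),
                      ae = character(0), n111 = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(multi)) return(empty)
  pair_list <- lapply(reports$drugs[multi], function(d) {
    utils::combn(sort(d, method = "radix"), 2L)
  })
  aes_multi <- reports$aes[multi]
  n_pairs <- vapply(pair_list, ncol, integer(1))
  n_aes <- lengths(aes_multi)
  long <- data.table::data.table(
    drug1 = unlist(Map(function(p, na) rep.int(p[1L, ], na), pair_list, n_aes),
                   use.names = FALSE),
    drug2 = unlist(Map(function(p, na) rep.int(p[2L, ], na), pair_list, n_aes),
                   use.names = FALSE),
    ae = rep.int(unlist(Map(function(a, k) rep(a, each = k), aes_multi, n_pairs),
                        use.names = FALSE), 1L)
  )
  tab <- long[, .(n111 = .N), by = .(drug1, drug2, ae)]
  tab <- tab[n111 >= min_n111]
  if (!nrow(tab)) return(empty)
  data.table::setorderv(tab, c("n111", "drug1", "drug2", "ae"),
                        order = c(-1L, 1L, 1L, 1L))
  out <- as.data.frame(tab)
  out$n111 <- as.integer(out$n111)
  out
}

# Membership index: for each term, the sorted integer ids of reports carrying
# it. All contingency cells for a triple reduce to intersection sizes, which
# keeps full scans over hundreds of candidates cheap.
report_index <- function(reports) {
  n <- nrow(reports)
  rid_drug <- data.table::data.table(
    rid = rep.int(seq_len(n), lengths(reports$drugs)),
    term = unlist(reports$drugs, use.names = FALSE)
  )
  rid_ae <- data.table::data.table(
    rid = rep.int(seq_len(n), lengths(reports$aes)),
    term = unlist(reports$aes, use.names = FALSE)
  )
  list(
    n = n,
    drug = if (nrow(rid_drug)) split(rid_drug$rid, rid_drug$term) else list(),
    ae = if (nrow(rid_ae)) split(rid_ae$rid, rid_ae$term) else list()
  )
}

intersect_size <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  sum(match(a, b, nomatch = 0L) > 0L)
}

cells_from_index <- function(idx, drug1, drug2, ae) {
  r1 <- idx$drug[[drug1]] %||% integer(0)
  r2 <- idx$drug[[drug2]] %||% integer(0)
  ra <- idx$ae[[ae]] %||% integer(0)
  both <- r1[match(r1, r2, nomatch = 0L) > 0L]
  n11p <- length(both)
  n10p <- length(r1) - n11p
  n01p <- length(r2) - n11p
  n00p <- idx$n - n11p - n10p - n01p
  n111 <- intersect_size(both, ra)
  n101 <- intersect_size(r1, ra) - n111
  n011 <- intersect_size(r2, ra) - n111
  n001 <- length(ra) - n111 - n101 - n011
  c(n111 = n111, n110 = n11p - n111,
    n101 = n101, n100 = n10p - n101,
    n011 = n011, n010 = n01p - n011,
    n001 = n001, n000 = n00p - n001)
}

#' Build the 4x2 contingency table for one (drug1, drug2, AE) triple
#'
#' Each report in the analysis set is classified into exactly one of eight
#' cells: the exposure row is determined by which of the two drugs appear in
#' its drug set (both / only drug1 / only drug2 / neither) and the column by
#' whether its AE set contains the target term (target AE / all other AEs).
#' Counting is at the report level: a report listing the target AE alongside
#' other AEs still counts once, in the target column. Membership is exact
#' equality of standardized terms — no hierarchy roll-up is attempted.
#'
#' @param reports an [srs_reports] object, or a prebuilt internal index.
#' @param drug1,drug2 the drug pair (order irrelevant).
#' @param ae the target adverse-event term.
#' @return A `ddi_table` object: named numeric vector of the eight cells plus
#'   margins `n11p`, `n10p`, `n01p`, `n00p` (exposure-row totals), `npp1`,
#'   `npp0` (column totals) and `nppp` (grand total).
#' @examples
#' r <- srs_reports("r1", drugs = list(c("A", "B")), aes = list("X"))
#' build_contingency(r, "A", "B", "X")
#' @export
build_contingency <- function(reports, drug1, drug2, ae) {
  idx <- if (inherits(reports, "srs_reports")) report_index(reports) else reports
  cells <- cells_from_index(idx, drug1, drug2, ae)
  as_ddi_table(cells, drug1 = drug1, drug2 = drug2, ae = ae)
}

as_ddi_table <- function(cells, drug1 = NA, drug2 = NA, ae = NA) {
  cells <- as.numeric(cells[c("n111", "n110", "n101", "n100",
                              "n011", "n010", "n001", "n000")])
  names(cells) <- c("n111", "n110", "n101", "n100", "n011", "n010", "n001", "n000")
  if (any(is.na(cells)) || any(cells < 0)) stop("invalid contingency cells")
  out <- c(cells,
           n11p = cells[["n111"]] + cells[["n110"]],
           n10p = cells[["n101"]] + cells[["n100"]],
           n01p = cells[["n011"]] + cells[["n010"]],
           n00p = cells[["n001"]] + cells[["n000"]],
           npp1 = cells[["n111"]] + cells[["n101"]] + cells[["n011"]] + cells[["n001"]],
           npp0 = cells[["n110"]] + cells[["n100"]] + cells[["n010"]] + cells[["n000"]])
  out <- c(out, nppp = sum(cells))
  structure(out, class = "ddi_table",
            triple = c(drug1 = drug1, drug2 = drug2, ae = ae))
}

#' Construct a 4x2 table directly from its eight cells
#'
#' Useful for testing and for re-analysing published tables.
#' @param n111,n110,n101,n100,n011,n010,n001,n000 non-negative report counts:
#'   first index = drug1 present, second = drug2 present, third = target AE
#'   (1) vs any other AE (0).
#' @return A `ddi_table`.
#' @export
ddi_table <- function(n111, n110, n101, n100, n011, n010, n001, n000) {
  as_ddi_table(c(n111 = n111, n110 = n110, n101 = n101, n100 = n100,
                 n011 = n011, n010 = n010, n001 = n001, n000 = n000))
}

#' @export
print.ddi_table <- function(x, ...) {
  tr <- attr(x, "triple")
  if (!all(is.na(tr))) {
    cat(sprintf("4x2 DDI contingency table: %s + %s -> %s\n",
                tr[["drug1"]], tr[["drug2"]], tr[["ae"]]))
  }
  m <- matrix(c(x[["n111"]], x[["n110"]], x[["n11p"]],
                x[["n101"]], x[["n100"]], x[["n10p"]],
                x[["n011"]], x[["n010"]], x[["n01p"]],
                x[["n001"]], x[["n000"]], x[["n00p"]],
                x[["npp1"]], x[["npp0"]], x[["nppp"]]),
              ncol = 3, byrow = TRUE,
              dimnames = list(c("both", "only drug1", "only drug2",
                                "neither", "total"),
                              c("target AE", "other AEs", "total")))
  print(m)
  invisible(x)
}

#' Dump contingency tables for a candidate list
#'
#' One row per triple with all eight cells, for audit output.
#' @param reports an [srs_reports] object.
#' @param candidates a candidate data.frame from [enumerate_candidates()].
#' @return A data.frame with the triple columns and the eight cell counts.
#' @export
contingency_dump <- function(reports, candidates) {
  idx <- report_index(reports)
  cells <- t(vapply(seq_len(nrow(candidates)), function(i) {
    cells_from_index(idx, candidates$drug1[i], candidates$drug2[i],
                     candidates$ae[i])
  }, numeric(8)))
  cbind(candidates[, c("drug1", "drug2", "ae")], as.data.frame(cells))
}
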