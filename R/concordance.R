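#' Per-category concordance between two variant-category assignments
#'
#' For each broad category c, counts the variants each assignment places in
#' c (`n_A`, `n_S`), the variants both place in c (`n_shared`), their union
#' (`n_union = n_A + n_S - n_shared`), and the derived rates
#' `match_rate_A = n_shared / n_A`, `match_rate_S = n_shared / n_S`,
#' `union_share = n_shared / n_union`. Keys present in only one assignment
#' count toward that side's totals and the union but never toward
#' `n_shared`; the complements `1 - match_rate` are the private-annotation
#' rates. Rates with a zero denominator are NA, never 0 or 100.
#'
#' @param assign_a,assign_s Named character vectors: variant key -> broad
#'   category.
#' @param categories Category vocabulary (rows of the table).
#' @return data.frame of class `concordance_table`, one row per category
#'   plus a "total" row of column sums; rates are proportions in [0, 1].
#' @export
compare_assignments <- function(assign_a, assign_s,
                                categories = broad_categories()) {
  keys <- union(names(assign_a), names(assign_s))
  a <- unname(assign_a[keys])
  s <- unname(assign_s[keys])
  bad <- setdiff(stats::na.omit(unique(c(a, s))), categories)
  if (length(bad))
    stop("assignment uses unknown categories: ", paste(bad, collapse = ", "))
  n_a <- vapply(categories, function(c) sum(a == c, na.rm = TRUE), 0L)
  n_s <- vapply(categories, function(c) sum(s == c, na.rm = TRUE), 0L)
  n_sh <- vapply(categories,
                 function(c) sum(a == c & s == c, na.rm = TRUE), 0L)
  tab <- data.frame(category = categories, n_A = n_a, n_S = n_s,
                    n_shared = n_sh, stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(category = "total", n_A = sum(n_a),
                               n_S = sum(n_s), n_shared = sum(n_sh)))
  tab$n_union <- tab$n_A + tab$n_S - tab$n_shared
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tab$match_rate_A <- rate(tab$n_shared, tab$n_A)
  tab$match_rate_S <- rate(tab$n_shared, tab$n_S)
  tab$union_share <- rate(tab$n_shared, tab$n_union)
  rownames(tab) <- NULL
  structure(tab, class = c("concordance_table", "data.frame"),
            n_keys = length(keys))
}

#' @export
print.concordance_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("match_rate_A", "match_rate_S", "union_share"))
    y[[col]] <- ifelse(is.na(y[[col]]), "NA",
                       sprintf("%.2f%%", 100 * y[[col]]))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a concordance report as TSV and JSON
#'
#' The TSV renders rates as percentages with two decimals (undefined rates
#' as "NA"); the JSON mirror carries raw counts and numeric rates for
#' machines. Re-parsing the TSV reproduces the counts exactly.
#'
#' @param tab A [compare_assignments()] table.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_concordance_report <- function(tab, prefix) {
  df <- as.data.frame(tab)
  out <- df
  for (col in c("match_rate_A", "match_rate_S", "union_share"))
    out[[col]] <- ifelse(is.na(df[[col]]), "NA",
                         sprintf("%.2f", 100 * df[[col]]))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  write_tsv(out, tsv)
  jsonlite::write_json(df, json, dataframe = "rows", na = "null",
                       digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Perturbation harness for the concordance statistics
#'
#' Re-draws each key's category independently in two copies of a truth
#' assignment (with probability `rate_a` / `rate_b`, uniformly over the
#' category vocabulary), compares them, and returns the observed agreement.
#' With both rates 1 the expected overall agreement has the closed form
#' 1/K for K categories, which makes [compare_assignments()] checkable
#' against an analytic value.
#'
#' @param truth Named character vector: key -> category.
#' @param rate_a,rate_b Re-draw probabilities in [0, 1].
#' @param seed Integer seed.
#' @param categories Category vocabulary used for re-drawing.
#' @return List: `table` (concordance_table), `overall_agreement`
#'   (fraction of keys assigned identically), `per_category` (union_share
#'   by category).
#' @export
planted_disagreement_check <- function(truth, rate_a, rate_b, seed,
                                       categories = broad_categories()) {
  maps <- perturb_assignments(truth, rate_a, rate_b, seed, categories)
  tab <- compare_assignments(maps$a, maps$b, categories)
  total <- tab[tab$category == "total", ]
  list(table = tab,
       overall_agreement = total$n_shared / length(truth),
       per_category = stats::setNames(
         tab$union_share[tab$category != "total"],
         tab$category[tab$category != "total"]))
}
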