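#' Build a 2x2 contingency table for a gene-list overlap
#'
#' Cell layout: `a` = overlap (query and target), `b` = query only,
#' `c` = target only, `d` = neither; `n = a + b + c + d` is the universe
#' size.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return a `ContingencyTable` list with fields `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_msg("contingency cells must be non-negative integers")
  }
  n <- a + b + c + d
  if (n <= 0) stop_msg("empty contingency table")
  structure(list(a = a, b = b, c = c, d = d, n = n),
            class = "ContingencyTable")
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Computes the continuity-corrected statistic
#' \deqn{\chi^2 = \frac{n\,(\max(0, |ad - bc| - n/2))^2}{(a+b)(c+d)(a+c)(b+d)}}
#' with the correction floored at zero (a table at exact independence gives
#' `chi2 = 0`, `p = 1`), and the upper-tail P value on 1 degree of freedom.
#' An expected cell below 5 appends a warning recommending the exact test.
#'
#' @param t a [contingency_table()].
#' @return list with `chi2`, `p`, and `warnings` (character vector).
#' @export
yates_chi_square <- function(t) {
  stopifnot(inherits(t, "ContingencyTable"))
  margins <- c(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d)
  if (any(margins == 0)) {
    stop_msg("zero margin in contingency table; use exact_overlap_p() instead")
  }
  n <- t$n
  num <- max(0, abs(t$a * t$d - t$b * t$c) - n / 2)
  chi2 <- n * num^2 / prod(margins)
  warnings <- character()
  expected <- outer(c(t$a + t$b, t$c + t$d), c(t$a + t$c, t$b + t$d)) / n
  if (any(expected < 5)) {
    warnings <- "expected cell count < 5; the exact test is more reliable"
  }
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       warnings = warnings)
}

#' Exact two-sided overlap P value (hypergeometric)
#'
#' Conditional on all four margins, sums the hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed table
#' (the two-sided exact convention). Serves as the exact companion and
#' validation oracle for [yates_chi_square()].
#'
#' @param t a [contingency_table()].
#' @return the two-sided exact P value.
#' @export
exact_overlap_p <- function(t) {
  stopifnot(inherits(t, "ContingencyTable"))
  m <- t$a + t$c          # target size
  nn <- t$b + t$d         # non-target size
  k <- t$a + t$b          # query size
  lo <- max(0L, k - nn)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(t$a, m, nn, k)
  # relative tolerance guards against ties lost to floating point
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Representation factor of an observed overlap
#'
#' `expected = size_a * size_b / universe_size`; `rf = observed / expected`.
#' The identity `rf * expected == observed` holds exactly.
#'
#' @param observed overlap size.
#' @param size_a,size_b sizes of the two gene lists.
#' @param universe_size size of the background universe.
#' @return list with `observed`, `expected`, `rf`.
#' @export
representation_factor <- function(observed, size_a, size_b, universe_size) {
  if (observed > min(size_a, size_b)) {
    stop_msg("observed overlap exceeds the smaller list")
  }
  if (size_a > universe_size || size_b > universe_size) {
    stop_msg("list larger than the universe")
  }
  if (universe_size < size_a + size_b - observed) {
    stop_msg("impossible configuration: universe smaller than the union")
  }
  expected <- size_a * size_b / universe_size
  list(observed = observed, expected = expected, rf = observed / expected)
}

#' Overlap enrichment from list sizes
#'
#' The numeric core shared by [gene_set_enrichment()] and
#' [cross_list_overlap()]: builds the contingency table from sizes, computes
#' the representation factor, the Yates-corrected chi-square P, the exact
#' hypergeometric P, and an exact Poisson 95% interval for the
#' representation factor. The universe size is a mandatory explicit
#' parameter and is echoed in the result: the expected overlap, hence every
#' P value, depends directly on it.
#'
#' @inheritParams representation_factor
#' @param conf_level confidence level of the RF interval (default 0.95).
#' @return an `EnrichmentResult` list: `observed`, `expected`, `rf`,
#'   `rf_ci`, `chi2`, `p_chi2`, `p_exact`, `universe_size`, `size_a`,
#'   `size_b`, `warnings`.
#' @export
overlap_enrichment <- function(observed, size_a, size_b, universe_size,
                               conf_level = 0.95) {
  rf <- representation_factor(observed, size_a, size_b, universe_size)
  tab <- contingency_table(observed, size_a - observed, size_b - observed,
                           universe_size - size_a - size_b + observed)
  p_exact <- exact_overlap_p(tab)
  margins_ok <- all(c(tab$a + tab$b, tab$c + tab$d,
                      tab$a + tab$c, tab$b + tab$d) > 0)
  if (margins_ok) {
    ch <- yates_chi_square(tab)
  } else {
    ch <- list(chi2 = NA_real_, p = NA_real_,
               warnings = "zero margin: chi-square undefined, exact P reported")
  }
  alpha <- 1 - conf_level
  rf_ci <- c(
    lo = if (observed == 0) 0 else stats::qgamma(alpha / 2, observed) / rf$expected,
    hi = stats::qgamma(1 - alpha / 2, observed + 1) / rf$expected
  )
  structure(
    list(observed = observed, expected = rf$expected, rf = rf$rf,
         rf_ci = rf_ci, chi2 = ch$chi2, p_chi2 = ch$p, p_exact = p_exact,
         universe_size = universe_size, size_a = size_a, size_b = size_b,
         warnings = ch$warnings),
    class = "EnrichmentResult"
  )
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "overlap %d of %d x %d in universe N = %d\n  expected %.2f, RF = %.3f [%.3f, %.3f]\n  chi2 = %.4g (Yates), P = %.3g; exact P = %.3g\n",
    x$observed, x$size_a, x$size_b, x$universe_size, x$expected, x$rf,
    x$rf_ci[1], x$rf_ci[2], x$chi2, x$p_chi2, x$p_exact))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' Gene-set over-representation of a query list against a target set
#'
#' The target set is intersected with the universe before testing; the query
#' must be a subset of the universe. The universe (background) must be
#' stated explicitly — it is the set of genes eligible to appear in either
#' list, and the reported P values are sensitive to its size.
#'
#' @param query character vector of query gene ids (e.g. a response class).
#' @param target character vector of target gene ids (e.g. polycomb targets).
#' @param universe character vector of background gene ids.
#' @inheritParams overlap_enrichment
#' @return an `EnrichmentResult`.
#' @export
gene_set_enrichment <- function(query, target, universe, conf_level = 0.95) {
  query <- unique(as.character(query))
  target <- unique(as.character(target))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop_msg("empty universe")
  if (length(query) == 0) stop_msg("empty query set")
  if (!all(query %in% universe)) {
    stop_msg("%d query gene(s) outside the universe", sum(!query %in% universe))
  }
  target <- intersect(target, universe)
  overlap_enrichment(length(intersect(query, target)),
                     length(query), length(target), length(universe),
                     conf_level = conf_level)
}

#' Cross-list overlap enrichment with an explicit universe size
#'
#' Overlap of two gene lists (e.g. positive-response lists from two cell
#' lines) against the chance expectation in a stated universe.
#'
#' @param list_a,list_b character vectors of gene ids.
#' @param universe_size integer size of the shared background universe.
#' @inheritParams overlap_enrichment
#' @return an `EnrichmentResult`.
#' @export
cross_list_overlap <- function(list_a, list_b, universe_size,
                               conf_level = 0.95) {
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  overlap_enrichment(length(intersect(list_a, list_b)),
                     length(list_a), length(list_b), universe_size,
                     conf_level = conf_level)
}

#' Combine gene sets by intersection or union
#'
#' `mode = "all"` returns genes in every set (targets of *all* components);
#' `mode = "at_least_one"` returns the union (targets of *at least one*).
#'
#' @param sets list of character vectors.
#' @param mode `"all"` or `"at_least_one"`.
#' @return character vector.
#' @export
combine_gene_sets <- function(sets, mode = c("all", "at_least_one")) {
  mode <- match.arg(mode)
  stopifnot(length(sets) >= 1)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  Reduce(if (mode == "all") intersect else union, sets)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop_msg("malformed GMT line %d in %s", short[1], path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
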