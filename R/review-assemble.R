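#' Validate a labeled content corpus
#'
#' The content corpus is a data frame with one row per app page:
#' `page_id` (unique), `category` (one of the daily-review categories),
#' `role` (`first`, `middle`, `last`, or `crisis`), `position` (2..5 for
#' middle pages, `NA` otherwise), `variant` (integer within role/position),
#' `next_id` (page id of a chained unique page, or `NA`), `target` and
#' `determinant` labels, and `tier` (1..3). Every non-crisis category must
#' provide at least one first-page and one last-page variant; crisis
#' categories consist of exactly one single `crisis` page.
#'
#' @param corpus content corpus data frame.
#' @return the corpus, invisibly, or an error describing the defect.
#' @export
validate_corpus <- function(corpus) {
  need <- c("page_id", "category", "role", "position", "variant",
            "next_id", "target", "determinant", "tier")
  missing <- setdiff(need, names(corpus))
  if (length(missing))
    stop("corpus missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(corpus$page_id))
    stop("corpus page_id values must be unique")
  lab <- c("category", "role", "target", "determinant", "tier")
  for (col in lab) {
    bad <- is.na(corpus[[col]]) | corpus[[col]] == ""
    if (any(bad))
      stop("unlabeled page(s) in corpus: missing ", col, " for ",
           paste(corpus$page_id[bad], collapse = ", "))
  }
  if (!all(corpus$role %in% c("first", "middle", "last", "crisis")))
    stop("corpus role must be first/middle/last/crisis")
  if (!all(corpus$tier %in% 1:3)) stop("corpus tier must be 1, 2, or 3")
  chained <- !is.na(corpus$next_id)
  if (any(chained & !corpus$next_id %in% corpus$page_id))
    stop("corpus next_id refers to unknown page(s)")
  for (cat in unique(corpus$category)) {
    rows <- corpus[corpus$category == cat, , drop = FALSE]
    if (any(rows$role == "crisis")) {
      if (nrow(rows) != 1L)
        stop("crisis category ", cat, " must consist of exactly one page")
    } else {
      if (!any(rows$role == "first") || !any(rows$role == "last"))
        stop("category ", cat, " needs at least one first-page and one ",
             "last-page variant")
    }
  }
  invisible(corpus)
}

#' Assemble the randomized daily-review page sequence
#'
#' Builds the 3--6-page daily review for a selected content category: the
#' first page carries the category feedback and the goal-achievement bar-graph
#' data; pages 2--5 are drawn per position, sampling uniformly among variants
#' except where a previously shown page chains to a unique follow-up page
#' (`next_id`), which is then taken deterministically; the last page
#' reiterates the category. Crisis categories emit exactly one page with no
#' bar graphs. Sampling avoids immediately repeating the previously shown
#' first/last variant when an alternative exists, and is deterministic under
#' a fixed seed.
#'
#' @param decision a `livewell_decision` from [select_category()].
#' @param corpus a validated content corpus (see [validate_corpus()]).
#' @param feedback bar-graph percentages from [goal_feedback()] (ignored for
#'   crisis categories).
#' @param seed integer seed for the page randomization.
#' @param previous optional list with `first` and `last` page ids shown the
#'   previous time this category was delivered.
#' @return Data frame of the selected pages in display order, with a
#'   `bar_graphs` logical column (TRUE only on non-crisis first pages) and the
#'   feedback attached as attribute `"feedback"`.
#' @export
assemble_review <- function(decision, corpus, feedback = NULL, seed = NULL,
                            previous = NULL) {
  validate_corpus(corpus)
  rows <- corpus[corpus$category == decision$category, , drop = FALSE]
  if (!nrow(rows))
    stop("category missing from corpus: ", decision$category)
  if (any(rows$role == "crisis")) {
    out <- rows[rows$role == "crisis", , drop = FALSE]
    out$bar_graphs <- FALSE
    rownames(out) <- NULL
    return(out)
  }
  runif_local <- local_rng(seed)
  pick <- function(cand, avoid = NULL) {
    if (!is.null(avoid) && nrow(cand) > 1L)
      cand <- cand[cand$page_id != avoid, , drop = FALSE]
    cand[floor(runif_local() * nrow(cand)) + 1L, , drop = FALSE]
  }
  first <- pick(rows[rows$role == "first", , drop = FALSE], previous$first)
  middle_rows <- rows[rows$role == "middle", , drop = FALSE]
  pages <- first
  pending <- first$next_id
  for (p in sort(unique(middle_rows$position))) {
    if (nrow(pages) >= 5L) break  # room must remain for the last page
    cand <- middle_rows[middle_rows$position == p, , drop = FALSE]
    chosen <- if (!is.na(pending) && pending %in% cand$page_id)
      cand[cand$page_id == pending, , drop = FALSE] else pick(cand)
    pages <- rbind(pages, chosen)
    pending <- chosen$next_id
  }
  pages <- rbind(pages, pick(rows[rows$role == "last", , drop = FALSE],
                             previous$last))
  pages$bar_graphs <- c(TRUE, rep(FALSE, nrow(pages) - 1L))
  rownames(pages) <- NULL
  attr(pages, "feedback") <- feedback
  pages
}

# seeded uniform sampler that never disturbs the caller's RNG state
local_rng <- function(seed) {
  if (is.null(seed)) return(function() stats::runif(1))
  state <- NULL
  local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  function() {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", state, envir = globalenv())
    u <- stats::runif(1)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    u
  }
}

#' Corpus label statistics
#'
#' Per-tier shares of the corpus pages and, within each tier, the
#' distribution of target and determinant labels -- the quantification used
#' to characterize how content shifts toward managing signs and symptoms in
#' the upper tiers. Shares are percentages and sum to 100 within each
#' partition.
#'
#' @param corpus a validated content corpus.
#' @return A list: `tier_shares` (named numeric, percent of pages per tier)
#'   and `targets` / `determinants` (lists, one named percent vector per
#'   tier).
#' @examples
#' corpus <- generate_corpus(tier_shares = c(0.71, 0.22, 0.07), n_pages = 100)
#' corpus_stats(corpus)$tier_shares
#' @export
corpus_stats <- function(corpus) {
  validate_corpus(corpus)
  n <- nrow(corpus)
  tier_tab <- table(factor(corpus$tier, levels = 1:3))
  tier_shares <- 100 * as.numeric(tier_tab) / n
  names(tier_shares) <- paste0("tier", 1:3)
  dist <- function(col) {
    lapply(stats::setNames(1:3, paste0("tier", 1:3)), function(tt) {
      rows <- corpus[corpus$tier == tt, , drop = FALSE]
      if (!nrow(rows)) return(numeric(0))
      tab <- sort(table(rows[[col]]), decreasing = TRUE)
      stats::setNames(100 * as.numeric(tab) / nrow(rows), names(tab))
    })
  }
  list(tier_shares = tier_shares, targets = dist("target"),
       determinants = dist("determinant"))
}
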