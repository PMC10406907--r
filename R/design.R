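# Block-structured design matrices.
#
# Every variable contributes one column block: binary and continuous variables
# one column, a categorical variable with c categories c-1 reference-coded
# columns (reference = first listed category). All columns are centered on the
# training rows; the centering constants are stored so test rows can be mapped
# through the identical transformation. Interaction blocks are elementwise
# products of the parents' *uncentered* columns, centered afterwards.

# Build raw (uncentered) main-effect columns for `data` under `dictionary`.
# Returns list(values, blocks) with blocks carrying id/kind/vars/cols/levels.
raw_main_columns <- function(data, dictionary) {
  n <- nrow(data)
  cols <- list()
  blocks <- list()
  names_out <- character(0)
  at <- 0L
  for (i in seq_len(nrow(dictionary))) {
    v <- dictionary$variable[i]
    if (!v %in% names(data))
      stop("variable '", v, "' in dictionary but not in data")
    x <- data[[v]]
    if (anyNA(x)) stop("variable '", v, "' contains missing values")
    type <- dictionary$type[i]
    if (type == "continuous") {
      block <- matrix(as.numeric(x), ncol = 1,
                      dimnames = list(NULL, v))
      lev <- NULL
    } else {
      cats <- dictionary$categories[[i]]
      x <- as.character(x)
      bad <- setdiff(unique(x), cats)
      if (length(bad))
        stop("variable '", v, "' has undeclared categor",
             if (length(bad) > 1) "ies: " else "y: ",
             paste(bad, collapse = ", "))
      lev <- cats[-1]  # reference = first listed category
      block <- vapply(lev, function(cat) as.numeric(x == cat), numeric(n))
      block <- matrix(block, nrow = n,
                      dimnames = list(NULL, paste0(v, "=", lev)))
    }
    idx <- at + seq_len(ncol(block))
    at <- at + ncol(block)
    cols[[length(cols) + 1L]] <- block
    names_out <- c(names_out, colnames(block))
    blocks[[v]] <- list(id = v, kind = "main", vars = v, cols = idx,
                        levels = lev)
  }
  values <- do.call(cbind, cols)
  colnames(values) <- names_out
  list(values = values, blocks = blocks)
}

#' Build a centered, block-structured design matrix
#'
#' Converts a tabular dataset plus its data dictionary into the numeric design
#' matrix used by all boosting models: one reference-coded column block per
#' variable, every column centered on the supplied (training) rows. The
#' centering constants are retained so that new data can be mapped with
#' [apply_design()] without re-centering.
#'
#' @param data data frame holding (at least) every dictionary variable.
#' @param dictionary a `boost_dictionary`; see [as_dictionary()].
#' @return an object of class `boost_design` with elements `values` (n x p
#'   centered matrix), `blocks` (per-term bookkeeping: id, kind, source
#'   variables, column indices), `column_means`, and the dictionary.
#' @examples
#' d <- as_dictionary(data.frame(
#'   variable = "irrigated", type = "binary",
#'   categories = I(list(c("no", "yes"))), group = "biophysical",
#'   is_moderator = FALSE))
#' dat <- data.frame(irrigated = c("no", "yes", "yes", "no"))
#' build_design(dat, d)$values
#' @export
build_design <- function(data, dictionary) {
  dictionary <- as_dictionary(dictionary)
  raw <- raw_main_columns(data, dictionary)
  sds <- apply(raw$values, 2, stats::sd)
  if (any(sds == 0)) {
    const <- unique(unlist(lapply(raw$blocks, function(b)
      if (any(sds[b$cols] == 0)) b$vars)))
    stop("constant design column(s) for variable(s): ",
         paste(const, collapse = ", "),
         " (degrees-of-freedom calibration undefined)")
  }
  mu <- colMeans(raw$values)
  values <- sweep(raw$values, 2, mu, "-")
  structure(list(values = values, blocks = raw$blocks, column_means = mu,
                 dictionary = dictionary, n = nrow(values),
                 p = ncol(values)),
            class = "boost_design")
}

#' @export
print.boost_design <- function(x, ...) {
  kinds <- vapply(x$blocks, `[[`, "", "kind")
  cat("boost_design: ", x$n, " observations, ", x$p, " columns, ",
      sum(kinds == "main"), " main blocks",
      if (any(kinds == "interaction"))
        paste0(", ", sum(kinds == "interaction"), " interaction blocks"),
      "\n", sep = "")
  invisible(x)
}

# Product columns for one interaction term from raw (uncentered) main columns.
interaction_product <- function(raw_values, mblock, pblock) {
  mc <- mblock$cols; pc <- pblock$cols
  M <- raw_values[, mc, drop = FALSE]
  P <- raw_values[, pc, drop = FALSE]
  out <- M[, rep(seq_along(mc), times = length(pc)), drop = FALSE] *
    P[, rep(seq_along(pc), each = length(mc)), drop = FALSE]
  colnames(out) <- paste(
    colnames(M)[rep(seq_along(mc), times = length(pc))],
    colnames(P)[rep(seq_along(pc), each = length(mc))], sep = ":")
  out
}

#' Enumerate and build moderator-by-variable interaction terms
#'
#' Forms one interaction term per unordered pair \{moderator, other variable\};
#' pairs of two moderators are included once (a documented choice, switchable
#' via `moderator_pairs`). Each term's columns are elementwise products of the
#' parents' uncentered main-effect columns, centered afterwards, so a term for
#' two binary parents is a single column and a moderator block of width a with
#' a partner block of width b yields an a*b-column block. With q moderators
#' among p variables this gives q(p-q) + q(q-1)/2 terms, the "p > n" regime
#' once expanded.
#'
#' @param design a `boost_design` from [build_design()].
#' @param moderator_pairs include moderator-moderator pairs (default TRUE).
#' @return object of class `boost_interactions`: centered `values`, per-term
#'   `blocks`, `column_means`, and a `terms` data frame (moderator, partner,
#'   id). Zero flagged moderators yield an empty term list with a warning.
#' @export
build_interactions <- function(design, moderator_pairs = TRUE) {
  stopifnot(inherits(design, "boost_design"))
  dict <- design$dictionary
  mods <- dict$variable[dict$is_moderator]
  if (!length(mods)) {
    warning("no moderator variables flagged; no interaction terms built")
    return(structure(list(values = design$values[, 0, drop = FALSE],
                          blocks = list(), column_means = numeric(0),
                          terms = data.frame(moderator = character(0),
                                             partner = character(0),
                                             id = character(0))),
                     class = "boost_interactions"))
  }
  raw <- sweep(design$values, 2, design$column_means, "+")
  seen <- character(0)
  pieces <- list(); blocks <- list()
  terms <- list()
  at <- 0L
  for (m in mods) {
    partners <- setdiff(dict$variable, m)
    for (v in partners) {
      if (dict$is_moderator[match(v, dict$variable)]) {
        if (!moderator_pairs) next
        key <- paste(sort(c(m, v)), collapse = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
      }
      prod <- interaction_product(raw, design$blocks[[m]], design$blocks[[v]])
      id <- paste0(m, ":", v)
      idx <- at + seq_len(ncol(prod))
      at <- at + ncol(prod)
      pieces[[id]] <- prod
      blocks[[id]] <- list(id = id, kind = "interaction", vars = c(m, v),
                           cols = idx, levels = NULL)
      terms[[id]] <- data.frame(moderator = m, partner = v, id = id,
                                stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, pieces)
  mu <- colMeans(values)
  structure(list(values = sweep(values, 2, mu, "-"), blocks = blocks,
                 column_means = mu,
                 terms = do.call(rbind, c(terms, make.row.names = FALSE))),
            class = "boost_interactions")
}

#' Append interaction blocks to a design
#'
#' @param design a `boost_design`.
#' @param interactions a `boost_interactions` built from the same design.
#' @return a `boost_design` whose matrix holds the main-effect columns followed
#'   by the interaction columns, with block bookkeeping merged.
#' @export
combine_design <- function(design, interactions) {
  stopifnot(inherits(design, "boost_design"),
            inherits(interactions, "boost_interactions"))
  off <- ncol(design$values)
  iblocks <- lapply(interactions$blocks, function(b) {
    b$cols <- b$cols + off
    b
  })
  values <- cbind(design$values, interactions$values)
  structure(list(values = values,
                 blocks = c(design$blocks, iblocks),
                 column_means = c(design$column_means,
                                  interactions$column_means),
                 dictionary = design$dictionary,
                 n = nrow(values), p = ncol(values)),
            class = "boost_design")
}

#' Map new data through an existing design
#'
#' Applies the training-time construction (reference coding, interaction
#' products, centering with the *training* column means) to new rows. Unseen
#' categories are rejected; applying a design to its own training data
#' reproduces `design$values` exactly.
#'
#' @param design a `boost_design` (possibly with interaction blocks).
#' @param newdata data frame with the dictionary variables.
#' @return an n' x p numeric matrix aligned with `design$values`.
#' @export
apply_design <- function(design, newdata) {
  stopifnot(inherits(design, "boost_design"))
  raw <- raw_main_columns(newdata, design$dictionary)
  out <- matrix(0, nrow(raw$values), design$p)
  nm <- character(design$p)
  for (b in design$blocks) {
    if (b$kind == "main") {
      piece <- raw$values[, raw$blocks[[b$vars]]$cols, drop = FALSE]
    } else {
      piece <- interaction_product(raw$values, raw$blocks[[b$vars[1]]],
                                   raw$blocks[[b$vars[2]]])
    }
    out[, b$cols] <- piece
    nm[b$cols] <- colnames(piece)
  }
  colnames(out) <- nm
  sweep(out, 2, design$column_means, "-")
}
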