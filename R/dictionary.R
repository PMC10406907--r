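#' Read a data dictionary
#'
#' The dictionary assigns every analysis variable a type, its category labels,
#' a group label and a moderator flag. Moderator variables are the ones allowed
#' to form interaction terms with every other variable (the survey analogue of
#' flagging potential effect modifiers such as region, gender or education).
#'
#' @param path path to a CSV file with columns
#'   `variable,type,categories,group,is_moderator`; `categories` holds the
#'   ordered category labels separated by `|` (empty for continuous variables)
#'   and `is_moderator` is 0/1.
#' @return a validated data frame of class `boost_dictionary` with list-column
#'   `categories`.
#' @seealso [build_design()], [write_dictionary()]
#' @export
read_dictionary <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("variable", "type", "categories", "group", "is_moderator")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("dictionary is missing columns: ", paste(miss, collapse = ", "))
  as_dictionary(data.frame(
    variable = raw$variable,
    type = raw$type,
    categories = I(lapply(raw$categories, function(s) {
      if (!nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
    })),
    group = raw$group,
    is_moderator = as.integer(raw$is_moderator) == 1L,
    stringsAsFactors = FALSE
  ))
}

#' Write a data dictionary to CSV
#'
#' @param dictionary a `boost_dictionary` (see [as_dictionary()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  dictionary <- as_dictionary(dictionary)
  out <- data.frame(
    variable = dictionary$variable,
    type = dictionary$type,
    categories = vapply(dictionary$categories, paste, "", collapse = "|"),
    group = dictionary$group,
    is_moderator = as.integer(dictionary$is_moderator),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate a data dictionary
#'
#' Checks per-variable invariants: binary variables declare exactly two
#' categories, categorical ones at least two, continuous ones none; names are
#' unique and every variable carries a nonempty group label.
#'
#' @param x data frame with columns `variable`, `type`, `categories`
#'   (list-column of character vectors), `group`, `is_moderator`.
#' @return `x` with class `boost_dictionary` prepended.
#' @export
as_dictionary <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("variable", "type", "categories", "group", "is_moderator")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("dictionary is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$variable))
    stop("duplicate variable names in dictionary: ",
         paste(unique(x$variable[duplicated(x$variable)]), collapse = ", "))
  if (!all(x$type %in% c("binary", "categorical", "continuous")))
    stop("variable types must be one of binary, categorical, continuous")
  if (any(!nzchar(x$group)))
    stop("every variable needs a nonempty group label")
  ncat <- lengths(x$categories)
  bad <- (x$type == "binary" & ncat != 2L) |
    (x$type == "categorical" & ncat < 2L) |
    (x$type == "continuous" & ncat != 0L)
  if (any(bad))
    stop("invalid category declarations for: ",
         paste(x$variable[bad], collapse = ", "))
  x$is_moderator <- as.logical(x$is_moderator)
  class(x) <- unique(c("boost_dictionary", class(x)))
  x
}
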