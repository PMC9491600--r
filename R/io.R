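#' Read a reaction database
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`"equations"`}{Plain text, one equation per line in the
#'     [parse_reaction()] grammar; `#` starts a comment. An optional leading
#'     `<id>:` names the reaction, otherwise ids `r1`, `r2`, ... are
#'     assigned.}
#'   \item{`"table"`}{TSV/CSV with columns `reaction_id`, `equation` and
#'     optionally `catalysts` (comma-separated), `reversible`
#'     (true/false/1/0), `origin`.}
#'   \item{`"xlsx"`}{The same column layout read from the first sheet of an
#'     Excel workbook (requires the readxl package); supplementary reaction
#'     tables distributed as XLSX can be loaded this way, with unknown column
#'     layouts resolved by name matching.}
#' }
#'
#' @param path File to read.
#' @param dialect One of `"auto"`, `"equations"`, `"table"`, `"xlsx"`;
#'   `"auto"` picks by file extension (`.tsv`/`.csv`/`.txt`/`.xlsx`).
#' @param split Split reversible rows into `.a`/`.b` unidirectional halves
#'   (default `TRUE`).
#' @param species Optional species metadata data frame, as in
#'   [reaction_network()].
#' @return A `reaction_network`. An empty file yields an empty network.
#' @export
read_reaction_db <- function(path, dialect = c("auto", "equations", "table", "xlsx"),
                             split = TRUE, species = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, tsv = , csv = "table", xlsx = "xlsx", "equations")
  }
  rx <- switch(dialect,
    equations = read_equation_file(path),
    table = read_reaction_table(utils::read.delim(
      path, sep = if (tolower(tools::file_ext(path)) == "csv") "," else "\t",
      stringsAsFactors = FALSE, check.names = FALSE)),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the readxl package", call. = FALSE)
      read_reaction_table(as.data.frame(readxl::read_excel(path)))
    })
  reaction_network(rx, species = species, split = split)
}

read_equation_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    id <- sprintf("r%d", i)
    m <- regmatches(ln, regexec("^([^:|]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L && grepl("(->|<=>)", m[3])) {
      id <- trimws(m[2]); ln <- m[3]
    }
    out[[i]] <- parse_reaction(ln, id = id)
  }
  out
}

read_reaction_table <- function(df) {
  if (nrow(df) == 0L) return(list())
  names(df) <- tolower(trimws(names(df)))
  id_col <- intersect(c("reaction_id", "id", "reaction"), names(df))[1]
  eq_col <- intersect(c("equation", "reaction_equation", "eq"), names(df))[1]
  if (is.na(id_col) || is.na(eq_col))
    stop("reaction table needs 'reaction_id' and 'equation' columns; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- parse_reaction(as.character(df[[eq_col]][i]),
                        id = as.character(df[[id_col]][i]),
                        origin = if ("origin" %in% names(df))
                          as.character(df$origin[i]) else NA_character_)
    if ("catalysts" %in% names(df) && !is.na(df$catalysts[i]) &&
        nzchar(df$catalysts[i])) {
      extra <- trimws(strsplit(as.character(df$catalysts[i]), ",")[[1]])
      r$catalysts <- union(r$catalysts, extra[nzchar(extra)])
    }
    if ("reversible" %in% names(df)) {
      rv <- df$reversible[i]
      r$reversible <- if (is.na(rv)) r$reversible else
        isTRUE(rv) || tolower(as.character(rv)) %in% c("true", "t", "yes", "1")
    }
    r
  })
}

#' Write a reaction database
#'
#' @param net A `reaction_network`.
#' @param path Output file.
#' @param dialect `"table"` (TSV with `reaction_id`, `equation`, `catalysts`,
#'   `reversible`, `origin`) or `"equations"` (plain text). Loading the
#'   written file recovers the same stoichiometries, catalyst sets and ids.
#' @return `path`, invisibly.
#' @export
write_reaction_db <- function(net, path, dialect = c("table", "equations")) {
  stopifnot(inherits(net, "reaction_network"))
  dialect <- match.arg(dialect)
  rs <- net$reactions
  if (dialect == "equations") {
    writeLines(vapply(rs, function(r) paste0(r$id, ": ", format_reaction(r)),
                      character(1)), con = path, useBytes = TRUE)
  } else {
    df <- data.frame(
      reaction_id = vapply(rs, `[[`, character(1), "id"),
      equation = vapply(rs, function(r) {
        r2 <- r; r2$catalysts <- character(); format_reaction(r2)
      }, character(1)),
      catalysts = vapply(rs, function(r) paste(r$catalysts, collapse = ","),
                         character(1)),
      reversible = vapply(rs, function(r) isTRUE(r$reversible), logical(1)),
      origin = vapply(rs, function(r) {
        if (is.na(r$origin)) "" else r$origin
      }, character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}
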