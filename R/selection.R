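# Slash-style atom selections: /SEGID/RESID-SPEC/ATOM-SPEC
#
# Each field accepts "*" (match all), comma lists, and for the residue field
# numeric ranges written @(a-b).  The en-dash is accepted alongside the
# hyphen inside ranges.  The grammar is a minimal reconstruction of the
# original tool's selection syntax, which is documented only by example;
# anything beyond the three-field form above is an extension and is flagged
# as such in the vignette.

#' Resolve an atom selection expression
#'
#' @param structure a `trj_structure`
#' @param expression selection string `/SEG/RES/ATOM`; e.g. `"/*/*/CA"`,
#'   `"/*/@(1-10)/*"`, `"/A/1,3,5/CA,CB"`
#' @return a `trj_selection`: list with `expr` and strictly increasing
#'   unique atom `indices` (1-based).  An empty match is not an error.
#' @export
select_atoms <- function(structure, expression) {
  a <- structure$atoms
  fields <- parse_selection(expression)
  seg <- atom_seg(a)
  keep <- match_field_str(seg, fields$seg, expression) &
    match_field_res(a$resid, fields$res, expression) &
    match_field_str(a$name, fields$atom, expression)
  sel <- list(expr = expression, indices = which(keep))
  class(sel) <- "trj_selection"
  sel
}

parse_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1)
    stop("selection expression must be a single string")
  s <- trimws(expression)
  if (!startsWith(s, "/"))
    stop("selection syntax error: expected leading '/' in '", s, "'")
  body <- sub("^/", "", s)
  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("selection syntax error: expected /SEGID/RESID/ATOM, got '",
         s, "'")
  parts <- trimws(parts)
  if (any(parts == ""))
    stop("selection syntax error: empty field in '", s, "'")
  list(seg = parts[1], res = parts[2], atom = parts[3])
}

match_field_str <- function(values, spec, expr) {
  if (spec == "*") return(rep(TRUE, length(values)))
  items <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  if (any(items == ""))
    stop("selection syntax error at token '", spec, "'")
  keep <- rep(FALSE, length(values))
  for (it in items) {
    if (it == "*") keep <- keep | TRUE
    else keep <- keep | (toupper(values) == toupper(it))
  }
  keep
}

match_field_res <- function(resid, spec, expr) {
  if (spec == "*") return(rep(TRUE, length(resid)))
  items <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  keep <- rep(FALSE, length(resid))
  for (it in items) {
    if (it == "*") { keep <- keep | TRUE; next }
    if (grepl("^@\\(", it)) {
      # numeric range @(a-b); en-dash tolerated
      m <- regmatches(it, regexec("^@\\(([0-9]+)[-–]([0-9]+)\\)$", it))[[1]]
      if (length(m) != 3)
        stop("selection syntax error at token '", it, "'")
      lo <- as.integer(m[2]); hi <- as.integer(m[3])
      if (lo > hi) stop("selection syntax error: empty range in '", it, "'")
      keep <- keep | (resid >= lo & resid <= hi)
    } else if (grepl("^[0-9]+$", it)) {
      keep <- keep | (resid == as.integer(it))
    } else {
      stop("selection syntax error at token '", it, "'")
    }
  }
  keep
}

#' @export
print.trj_selection <- function(x, ...) {
  cat(sprintf("<trj_selection> '%s': %d atoms\n", x$expr, length(x$indices)))
  invisible(x)
}
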