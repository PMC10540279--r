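#' Parse an XYZ-format block into an XyzStructure
#'
#' Standard XYZ: line 1 is the atom count, line 2 a free comment, then
#' one `element x y z` line per atom (coordinates in Angstrom).  If the
#' comment line contains `ligand=<id>` and/or `role=<pro_R|pro_S>`
#' key=value fields they populate the corresponding metadata.
#'
#' @param text a single string (possibly multi-line) or a character
#'   vector of lines.
#' @return An [XyzStructure-class].
#' @examples
#' s <- parseXyz("4\nligand=L1 role=pro_S\nPd 0 0 0\nP 2 0 0\nC -1 1.5 0\nC -1 -1.5 0")
#' structureRole(s)
#' @seealso [writeXyz()]
#' @export
parseXyz <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else as.character(text)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines))
    stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("line 1 of an XYZ block must be a positive atom count, got: ",
         sQuote(trimws(lines[1])))
  if (length(lines) < n + 2L)
    stop(sprintf("XYZ block declares %d atoms but only %d atom lines follow",
                 n, max(0L, length(lines) - 2L)))
  extra <- lines[-seq_len(n + 2L)]
  if (any(nzchar(trimws(extra))))
    stop(sprintf("XYZ block declares %d atoms but more atom lines follow (line %d)",
                 n, n + 3L))
  comment <- lines[2]
  elements <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- n_line <- i + 2L
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) < 4)
      stop(sprintf("line %d: expected 'element x y z', got %s",
                   ln, sQuote(lines[ln])))
    elements[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(vals)))
      stop(sprintf("line %d: non-numeric coordinate in %s",
                   ln, sQuote(lines[ln])))
    xyz[i, ] <- vals
  }
  meta <- .parseXyzComment(comment)
  xyzStructure(elements, xyz, ligandId = meta$ligand, role = meta$role,
               comment = comment)
}

.parseXyzComment <- function(comment) {
  grab <- function(key) {
    m <- regmatches(comment,
                    regexpr(sprintf("%s=\\S+", key), comment))
    if (length(m) && nzchar(m)) sub(sprintf("^%s=", key), "", m)
    else NA_character_
  }
  role <- grab("role")
  if (!is.na(role) && !role %in% c("pro_R", "pro_S")) role <- NA_character_
  list(ligand = grab("ligand"), role = role)
}

#' Serialize an XyzStructure to XYZ text
#'
#' The comment line carries `ligand=` / `role=` metadata when set, so
#' that `parseXyz(writeXyz(s))` restores the structure (coordinates are
#' printed with 10 decimals).
#'
#' @param s an [XyzStructure-class].
#' @param path optional file to write to; when `NULL` the text is
#'   returned invisibly-visibly as a character scalar.
#' @return The XYZ text (invisibly when `path` is given).
#' @export
writeXyz <- function(s, path = NULL) {
  stopifnot(is(s, "XyzStructure"))
  meta <- character()
  if (!is.na(s@ligandId)) meta <- c(meta, paste0("ligand=", s@ligandId))
  if (!is.na(s@role)) meta <- c(meta, paste0("role=", s@role))
  comment <- if (length(meta)) paste(meta, collapse = " ") else s@comment
  body <- sprintf("%s %.10f %.10f %.10f", s@elements,
                  s@coords[, 1], s@coords[, 2], s@coords[, 3])
  text <- paste(c(length(s@elements), comment, body), collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Read all XYZ files of a directory as transition-state pairs
#'
#' Each `.xyz` file must carry `ligand=` and `role=` metadata on its
#' comment line.  Files are grouped by ligand; every ligand must have
#' exactly one pro_R and one pro_S structure.
#'
#' @param dir directory containing `.xyz` files.
#' @return A named list (one element per ligand) of
#'   `list(pro_R = , pro_S = )` [XyzStructure-class] pairs.
#' @export
readXyzDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xyz$", full.names = TRUE))
  if (!length(files)) stop("no .xyz files found in ", dir)
  structures <- lapply(files, function(f)
    parseXyz(readLines(f, warn = FALSE)))
  ids <- vapply(structures, function(s) s@ligandId, character(1))
  roles <- vapply(structures, function(s) s@role, character(1))
  if (any(is.na(ids)) || any(is.na(roles)))
    stop("every XYZ comment line must carry ligand= and role= metadata")
  out <- list()
  for (id in sort(unique(ids))) {
    sel <- which(ids == id)
    r <- roles[sel]
    if (!setequal(r, c("pro_R", "pro_S")) || length(sel) != 2)
      stop("ligand ", id, " must have exactly one pro_R and one pro_S ",
           "structure, found roles: ", paste(r, collapse = ", "))
    out[[id]] <- list(pro_R = structures[[sel[r == "pro_R"]]],
                      pro_S = structures[[sel[r == "pro_S"]]])
  }
  out
}
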