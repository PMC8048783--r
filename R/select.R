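#' Select atoms by attribute equality
#'
#' Resolves a small selection language against a trajectory roster (or a
#' roster-shaped tibble): a conjunction of equality tests joined by `&`, each
#' of the form `field=value`.  Fields are `name`, `element`, `resname`
#' (alias `residue_name`), `resnum` (alias `residue_number`) and `chain`.
#' A value may be a comma-separated list, which matches any of the listed
#' values (handy for water residue names, e.g. `resname=HOH,WAT,SOL`).
#'
#' @param x A [trajectory()] or a data frame with the roster columns.
#' @param expr Selection string, e.g. `"element=O & resname=HOH"`.
#' @return Sorted integer vector of roster indices (possibly empty).
#' @examples
#' ros <- tibble::tibble(serial = 1:3, name = c("O", "H1", "H2"),
#'                       element = c("O", "H", "H"), resname = "HOH",
#'                       resnum = 1L, chain = "A")
#' traj <- trajectory(ros, array(0, c(3, 3, 1)))
#' select_atoms(traj, "element=H & resname=HOH")
#' @export
select_atoms <- function(x, expr) {
  roster <- if (inherits(x, "trajectory")) x$roster else tibble::as_tibble(x)
  if (!is.character(expr) || length(expr) != 1 || !nzchar(trimws(expr))) {
    stop("selection syntax error: expr must be a non-empty string",
         call. = FALSE)
  }
  clauses <- strsplit(expr, "&", fixed = TRUE)[[1]]
  keep <- rep(TRUE, nrow(roster))
  aliases <- c(residue_name = "resname", residue_number = "resnum")
  for (cl in clauses) {
    cl <- trimws(cl)
    m <- regmatches(cl, regexec("^([A-Za-z_]+)\\s*=\\s*(\\S.*)$", cl))[[1]]
    if (length(m) != 3) {
      stop("selection syntax error in clause: '", cl, "'", call. = FALSE)
    }
    field <- m[2]
    if (field %in% names(aliases)) field <- aliases[[field]]
    if (!field %in% c("name", "element", "resname", "resnum", "chain")) {
      stop("selection syntax error: unknown field '", m[2], "'",
           call. = FALSE)
    }
    vals <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    col <- roster[[field]]
    if (field == "resnum") {
      v <- suppressWarnings(as.integer(vals))
      if (any(is.na(v))) {
        stop("selection syntax error: resnum values must be integers",
             call. = FALSE)
      }
      keep <- keep & (col %in% v)
    } else {
      keep <- keep & (as.character(col) %in% vals)
    }
  }
  which(keep)
}
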