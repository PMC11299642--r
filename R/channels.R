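#' Reaction channel tables
#'
#' A channel table is a data.frame (class \code{channel_table}) with one row
#' per candidate scavenging event (site x mechanism x radical) and columns:
#' \describe{
#'   \item{site}{site label, e.g. "C12", "C23-H"}
#'   \item{mechanism}{"FHT" (formal hydrogen transfer), "RAF" (radical adduct
#'     formation) or "SET" (single electron transfer)}
#'   \item{radical}{attacking radical, e.g. "HO", "HOO"}
#'   \item{dg_rxn}{reaction free energy, kcal mol^-1 (NA if unknown)}
#'   \item{dg_act}{activation free energy, kcal mol^-1, 1 M standard state}
#'   \item{kappa}{supplied tunneling correction, >= 1}
#'   \item{sigma}{reaction-path degeneracy, integer >= 1}
#'   \item{nu_imag, v_forward, v_reverse}{Eckart/Wigner tunneling inputs:
#'     imaginary-frequency magnitude (cm^-1) and forward/reverse barriers
#'     (kcal mol^-1)}
#'   \item{k_ref}{optional reference rate constant (M^-1 s^-1) carried along
#'     for comparison and aggregation of literature values}
#' }
#'
#' @param site,mechanism,radical Character vectors (recycled).
#' @param dg_rxn,dg_act,kappa,nu_imag,v_forward,v_reverse,k_ref Numeric,
#'   NA = absent.
#' @param sigma Integer degeneracy, default 1.
#' @return A validated \code{channel_table}.
#' @examples
#' channel_table(site = c("C12", "C23-H"), mechanism = c("RAF", "FHT"),
#'               radical = "HO", dg_rxn = c(-20.7, -21.7),
#'               dg_act = c(2.3, 4.1), kappa = c(1.2, 2.5), sigma = c(1, 3))
#' @export
channel_table <- function(site, mechanism, radical = "HO",
                          dg_rxn = NA_real_, dg_act = NA_real_,
                          kappa = NA_real_, sigma = 1L,
                          nu_imag = NA_real_, v_forward = NA_real_,
                          v_reverse = NA_real_, k_ref = NA_real_) {
  n <- length(site)
  rec <- function(x, mode = as.numeric) {
    x <- mode(x)
    if (length(x) == n) x else rep_len(x, n)
  }
  tab <- data.frame(
    site = as.character(site),
    mechanism = rec(mechanism, as.character),
    radical = rec(radical, as.character),
    dg_rxn = rec(dg_rxn),
    dg_act = rec(dg_act),
    kappa = rec(kappa),
    sigma = rec(sigma, as.integer),
    nu_imag = rec(nu_imag),
    v_forward = rec(v_forward),
    v_reverse = rec(v_reverse),
    k_ref = rec(k_ref),
    stringsAsFactors = FALSE
  )
  validate_channels(tab)
}

CHANNEL_MECHANISMS <- c("FHT", "RAF", "SET")

#' Validate a channel table
#'
#' Enforces the type invariants: known mechanism tokens, sigma >= 1,
#' kappa >= 1 when present, positive tunneling parameters when present,
#' no duplicate (site, mechanism, radical) key, and no activation energy on
#' SET rows (SET is screened thermodynamically only).
#'
#' @param tab A data.frame with channel columns.
#' @return The table, classed \code{channel_table}, invisibly checked.
#' @export
validate_channels <- function(tab) {
  stopifnot(is.data.frame(tab))
  needed <- c("site", "mechanism", "radical", "dg_rxn", "dg_act",
              "kappa", "sigma")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("channel table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("nu_imag", "v_forward", "v_reverse", "k_ref")) {
    if (is.null(tab[[col]])) tab[[col]] <- NA_real_
  }
  bad <- !(tab$mechanism %in% CHANNEL_MECHANISMS)
  if (any(bad)) {
    stop("unknown mechanism '", tab$mechanism[which(bad)[1]],
         "' in row ", which(bad)[1],
         " (expected FHT, RAF or SET)")
  }
  key <- paste(tab$site, tab$mechanism, tab$radical, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate channel (site, mechanism, radical): ",
         gsub("\r", "/", dup, fixed = TRUE))
  }
  if (any(is.na(tab$sigma)) || any(tab$sigma < 1)) {
    stop("sigma must be an integer >= 1 for every channel")
  }
  if (any(tab$kappa < 1, na.rm = TRUE)) {
    stop("kappa must be >= 1 when present")
  }
  for (col in c("nu_imag", "v_forward", "v_reverse")) {
    if (any(tab[[col]] <= 0, na.rm = TRUE)) {
      stop(col, " must be > 0 when present")
    }
  }
  set_with_act <- tab$mechanism == "SET" & !is.na(tab$dg_act)
  if (any(set_with_act)) {
    stop("SET channel '", tab$site[which(set_with_act)[1]],
         "' carries an activation energy; SET is screened by dg_rxn only")
  }
  class(tab) <- unique(c("channel_table", class(tab)))
  tab
}

#' Read a channel table from CSV
#'
#' Expects a comma-separated UTF-8 file with "." decimals and header columns
#' \code{site, mechanism, radical, dG_rxn, dG_act, kappa, sigma, nu_imag,
#' v_forward, v_reverse} (blank cell = absent; extra columns such as
#' \code{k_ref} are kept). Missing \code{sigma} defaults to 1.
#'
#' @param path CSV file path.
#' @return A \code{channel_table}.
#' @export
read_channels <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  needed <- c("site", "mechanism", "radical", "dG_rxn", "dG_act",
              "kappa", "sigma", "nu_imag", "v_forward", "v_reverse")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("channel CSV '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(col, name) {
    x <- trimws(raw[[col]])
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop("non-numeric value '", x[which(bad)[1]], "' for ", name,
           " in row ", which(bad)[1], " of ", path)
    }
    out
  }
  if (nrow(raw) == 0) {
    return(channel_table(site = character(0), mechanism = character(0)))
  }
  sigma <- num("sigma", "sigma")
  sigma[is.na(sigma)] <- 1
  k_ref <- if ("k_ref" %in% names(raw)) num("k_ref", "k_ref") else NA_real_
  channel_table(
    site = trimws(raw$site),
    mechanism = trimws(raw$mechanism),
    radical = trimws(raw$radical),
    dg_rxn = num("dG_rxn", "dG_rxn"),
    dg_act = num("dG_act", "dG_act"),
    kappa = num("kappa", "kappa"),
    sigma = as.integer(sigma),
    nu_imag = num("nu_imag", "nu_imag"),
    v_forward = num("v_forward", "v_forward"),
    v_reverse = num("v_reverse", "v_reverse"),
    k_ref = k_ref
  )
}

#' Write a channel table to CSV
#'
#' Emits the dialect \code{\link{read_channels}} accepts (round-trip safe).
#'
#' @param tab A \code{channel_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_channels <- function(tab, path) {
  tab <- validate_channels(tab)
  out <- data.frame(
    site = tab$site, mechanism = tab$mechanism, radical = tab$radical,
    dG_rxn = tab$dg_rxn, dG_act = tab$dg_act, kappa = tab$kappa,
    sigma = tab$sigma, nu_imag = tab$nu_imag, v_forward = tab$v_forward,
    v_reverse = tab$v_reverse, k_ref = tab$k_ref,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.channel_table <- function(x, ...) {
  cat("<channel_table> ", nrow(x), " channel(s); radicals: ",
      paste(unique(x$radical), collapse = ", "), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
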