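# Tabular readers/writers and packaged fixtures. All interchange is
# delimiter-configurable UTF-8 text with a required header and "." decimals.

read_table_pf <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop_pf("file not found: %s", path)
  read.csv(path, sep = delimiter, stringsAsFactors = FALSE,
           check.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a well-level transport table
#'
#' Reads and validates a delimited text file of well-level transwell
#' measurements, one row per replicate of one direction of one run. The
#' `area_cm2` column may be absent; the default insert area of 0.11 cm^2 is
#' then filled in for every row.
#'
#' @param path path to the delimited text file.
#' @param delimiter field delimiter, default `","`.
#' @return validated data.frame of transport records (row count preserved).
#' @seealso [write_transport_table()], [validate_transport_records()]
#' @export
read_transport_table <- function(path, delimiter = ",") {
  df <- read_table_pf(path, delimiter)
  n_in <- nrow(df)
  df <- validate_transport_records(df)
  pf_log("info", sprintf("read_transport_table: %d rows from %s", n_in, path))
  df
}

#' Write a transport table
#'
#' Inverse of [read_transport_table()]: the written file reads back into an
#' identical table (full printed precision for numeric columns).
#'
#' @param records validated transport records.
#' @param path output path.
#' @param delimiter field delimiter, default `","`.
#' @export
write_transport_table <- function(records, path, delimiter = ",") {
  records <- validate_transport_records(records)
  write.csv(records[, .TRANSPORT_COLS], path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a compound descriptor table
#'
#' Schema: `compound_id,name,mw,clogp,hbd,hba,solubility_uM`
#' (`solubility_uM` optional and may contain missing values).
#'
#' @inheritParams read_transport_table
#' @return validated data.frame.
#' @export
read_compound_table <- function(path, delimiter = ",") {
  df <- read_table_pf(path, delimiter)
  need <- c("compound_id", "name", "mw", "clogp", "hbd", "hba")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_pf("compound table is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  if (!"solubility_uM" %in% names(df)) df$solubility_uM <- NA_real_
  bad <- which(!is.na(df$mw) & df$mw <= 0)
  if (length(bad)) stop_pf("row %d: mw must be > 0", bad[1])
  bad <- which((!is.na(df$hbd) & df$hbd < 0) | (!is.na(df$hba) & df$hba < 0))
  if (length(bad)) stop_pf("row %d: hbd/hba must be >= 0", bad[1])
  df
}

#' Read a rodent PK summary table
#'
#' Schema: `compound_id,species,matrix,cl_L_per_h_kg,auc_iv,d_iv,auc_po,d_po`.
#' AUC units are arbitrary but must be identical within a row; species must
#' be `mouse` or `rat` (the only species with a packaged hepatic blood flow),
#' matrix `blood` or `plasma` (a blood:plasma ratio of 1 is assumed, so the
#' clearance is used as-is either way).
#'
#' @inheritParams read_transport_table
#' @return validated data.frame.
#' @export
read_pk_table <- function(path, delimiter = ",") {
  df <- read_table_pf(path, delimiter)
  need <- c("compound_id", "species", "matrix", "cl_L_per_h_kg",
            "auc_iv", "d_iv", "auc_po", "d_po")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_pf("PK table is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  bad <- !df$species %in% c("mouse", "rat")
  if (any(bad)) {
    stop_pf("row %d: unsupported species '%s'; supported: mouse, rat",
            which(bad)[1], df$species[which(bad)[1]])
  }
  bad <- !df$matrix %in% c("blood", "plasma")
  if (any(bad)) {
    stop_pf("row %d: unsupported matrix '%s'; supported: blood, plasma",
            which(bad)[1], df$matrix[which(bad)[1]])
  }
  if (any(df$cl_L_per_h_kg < 0)) {
    stop_pf("row %d: clearance must be >= 0", which(df$cl_L_per_h_kg < 0)[1])
  }
  for (col in c("auc_iv", "d_iv", "d_po")) {
    bad <- which(df[[col]] <= 0)
    if (length(bad)) stop_pf("row %d: %s must be > 0", bad[1], col)
  }
  if (any(df$auc_po < 0)) {
    stop_pf("row %d: auc_po must be >= 0", which(df$auc_po < 0)[1])
  }
  df
}

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "permaflow")
  if (p == "") stop_pf("packaged fixture '%s' is missing", file)
  p
}

# md5 digests pinning the packaged reference fixtures
.FIXTURE_MD5 <- c(
  reference_fa.csv = "54975da6e1bcb460f3696c630fca4624",
  preincubation_set.csv = "58c87585db88cd0dbf4e493830dc37c2"
)

.check_fixture <- function(file) {
  p <- .fixture_path(file)
  digest <- unname(tools::md5sum(p))
  if (!is.na(.FIXTURE_MD5[[file]]) && digest != .FIXTURE_MD5[[file]]) {
    stop_pf("packaged fixture '%s' failed its integrity check", file)
  }
  p
}

#' Load the packaged human fraction-absorbed reference list
#'
#' Returns the packaged 61-compound reference list of observed human
#' fraction absorbed (f_a) values (rounded to two significant figures). The
#' fixture is pinned by an md5 checksum.
#'
#' @return data.frame with columns `name` and `fa_obs` (fraction in
#'   \[0, 1\]).
#' @export
#' @examples
#' fa <- load_reference_fa()
#' fa$fa_obs[fa$name == "Hydroxychloroquine"]
load_reference_fa <- function() {
  df <- read.csv(.check_fixture("reference_fa.csv"),
                 stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (anyDuplicated(df$name)) stop_pf("reference f_a fixture has duplicate names")
  if (any(df$fa_obs < 0 | df$fa_obs > 1)) {
    stop_pf("reference f_a fixture contains values outside [0, 1]")
  }
  df
}

#' Load the packaged pre-incubation evaluation compound set
#'
#' Returns the packaged 21-compound set (10 named reference compounds plus
#' 11 internal compounds) used to evaluate the pre-incubation setup.
#' Internal compounds carry only descriptor bounds (for example a molecular
#' weight reported as ">700"), encoded as interval columns
#' `mw_lower`/`mw_upper` and `clogp_lower`/`clogp_upper`; an open side is
#' `NA`. Point values have both bounds equal. No point values are ever
#' fabricated for bounded descriptors.
#'
#' @return data.frame with columns `name`, `mw_lower`, `mw_upper`,
#'   `clogp_lower`, `clogp_upper`, `lipinski_class`.
#' @export
load_preincubation_set <- function() {
  df <- read.csv(.check_fixture("preincubation_set.csv"),
                 stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(df$lipinski_class %in% c("Ro5", "bRo5")))
  df
}
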