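#' Parse a karyotype formula
#'
#' A karyotype formula (KF) pools chromosomes into two centromere-position
#' classes: bi-armed meta-/submetacentrics (`m-sm`) and uni-armed
#' subtelo-/acrocentrics (`st-a`). Accepted dialect: `"<N>m-sm/<M>st-a"`,
#' `"<N>m-sm"` or `"<M>st-a"`; an absent class counts 0.
#'
#' @param text KF string, e.g. `"38m-sm/2st-a"`.
#' @return Named integer vector with elements `biarmed` and `uniarmed`.
#' @examples
#' parse_karyotype_formula("38m-sm/2st-a")
#' parse_karyotype_formula("38st-a")
#' @export
parse_karyotype_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (grepl("^([0-9]+)m-sm/([0-9]+)st-a$", s)) {
    m <- regmatches(s, regexec("^([0-9]+)m-sm/([0-9]+)st-a$", s))[[1]]
    out <- c(biarmed = as.integer(m[2]), uniarmed = as.integer(m[3]))
  } else if (grepl("^([0-9]+)m-sm$", s)) {
    out <- c(biarmed = as.integer(sub("m-sm$", "", s)), uniarmed = 0L)
  } else if (grepl("^([0-9]+)st-a$", s)) {
    out <- c(biarmed = 0L, uniarmed = as.integer(sub("st-a$", "", s)))
  } else {
    # name the first token that breaks the dialect
    tok <- strsplit(s, "/", fixed = TRUE)[[1]]
    bad <- tok[!grepl("^[0-9]+(m-sm|st-a)$", tok)]
    stop("malformed karyotype formula: offending token ",
         sQuote(if (length(bad)) bad[1] else s), call. = FALSE)
  }
  out
}

#' Serialize arm-class counts back to a karyotype formula
#'
#' @param biarmed,uniarmed Non-negative integer counts.
#' @return A KF string in the same dialect accepted by
#'   [parse_karyotype_formula()].
#' @export
format_karyotype_formula <- function(biarmed, uniarmed) {
  stopifnot(biarmed >= 0, uniarmed >= 0, biarmed + uniarmed > 0)
  if (uniarmed == 0L) return(sprintf("%dm-sm", biarmed))
  if (biarmed == 0L) return(sprintf("%dst-a", uniarmed))
  sprintf("%dm-sm/%dst-a", biarmed, uniarmed)
}

ch_position_codes <- c(cen = "centromeric", peri = "pericentromeric",
                       prox = "proximal", int = "interstitial",
                       dist = "distal", whole = "whole_arm")

#' Parse constitutive-heterochromatin band codes
#'
#' Bands are semicolon-separated `position:site` codes, e.g.
#' `"cen:all;int:2q;prox:7q;dist:9p"`. `site` is either `all` (a
#' whole-karyotype band, stored with `chromosome_pair = 0` and
#' `arm = "whole"`) or a 1-based chromosome pair index followed by an
#' optional arm letter `p`/`q`. Positions: `cen`, `peri`, `prox`, `int`,
#' `dist`, `whole` (whole-arm block).
#'
#' @param text Band code string; `""` or `NA` give zero bands.
#' @return A data.frame with columns `chromosome_pair`, `arm`, `position`.
#' @export
parse_ch_bands <- function(text) {
  empty <- data.frame(chromosome_pair = integer(), arm = character(),
                      position = character(), stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(empty)
  toks <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  rows <- lapply(toks, function(tok) {
    bits <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(bits) != 2L || !bits[1] %in% names(ch_position_codes))
      stop("malformed CH band code: ", sQuote(tok), call. = FALSE)
    pos <- ch_position_codes[[bits[1]]]
    site <- bits[2]
    if (site == "all") {
      data.frame(chromosome_pair = 0L, arm = "whole", position = pos,
                 stringsAsFactors = FALSE)
    } else {
      m <- regmatches(site, regexec("^([0-9]+)([pq]?)$", site))[[1]]
      if (length(m) == 0L)
        stop("malformed CH band site: ", sQuote(tok), call. = FALSE)
      data.frame(chromosome_pair = as.integer(m[2]),
                 arm = if (nzchar(m[3])) m[3] else "whole",
                 position = pos, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(list(empty), rows))
}

#' Serialize a CH band table back to its code string
#' @param bands Data.frame as returned by [parse_ch_bands()].
#' @return Semicolon-separated band code string.
#' @export
format_ch_bands <- function(bands) {
  if (is.null(bands) || nrow(bands) == 0L) return("")
  code <- names(ch_position_codes)[match(bands$position, ch_position_codes)]
  site <- ifelse(bands$chromosome_pair == 0L, "all",
                 paste0(bands$chromosome_pair,
                        ifelse(bands$arm == "whole", "", bands$arm)))
  paste(paste0(code, ":", site), collapse = ";")
}

#' Construct a karyotype record
#'
#' One species/sex karyotype: diploid number (2n), arm-class counts,
#' fundamental number (FN, total chromosome arms: bi-armed chromosomes
#' contribute 2 arms, uni-armed 1, so FN = 2n + bi-armed count), CH bands
#' and an optional sex-chromosome system tag.
#'
#' @param species Species name.
#' @param diploid_number 2n, a positive integer (>= 2).
#' @param karyotype_formula KF string; alternatively give `biarmed` and
#'   `uniarmed` directly.
#' @param biarmed,uniarmed Arm-class counts (must sum to `diploid_number`).
#' @param sex One of `"female"`, `"male"`, `"unspecified"`.
#' @param ch_bands Band code string (see [parse_ch_bands()]) or a band
#'   data.frame.
#' @param sex_system Optional sex-chromosome system tag, e.g.
#'   `"X1X1X2X2/X1X2Y"`.
#' @return An object of class `karyotype_record`.
#' @examples
#' karyotype_record("B. batesi", 40, "38m-sm/2st-a",
#'                  ch_bands = "cen:all;int:2q;prox:7q;dist:9p")
#' @export
karyotype_record <- function(species, diploid_number, karyotype_formula = NULL,
                             biarmed = NULL, uniarmed = NULL,
                             sex = c("unspecified", "female", "male"),
                             ch_bands = NULL, sex_system = NA_character_) {
  sex <- match.arg(sex)
  diploid_number <- as.integer(diploid_number)
  if (!is.null(karyotype_formula)) {
    cnt <- parse_karyotype_formula(karyotype_formula)
    biarmed <- cnt[["biarmed"]]; uniarmed <- cnt[["uniarmed"]]
  }
  if (is.null(biarmed) || is.null(uniarmed))
    stop("give either a karyotype_formula or both biarmed and uniarmed")
  biarmed <- as.integer(biarmed); uniarmed <- as.integer(uniarmed)
  if (diploid_number < 2L) stop("diploid_number must be >= 2")
  if (biarmed < 0L || uniarmed < 0L) stop("arm-class counts must be >= 0")
  if (biarmed + uniarmed != diploid_number)
    stop("arm-class counts (", biarmed, " + ", uniarmed,
         ") must sum to the diploid number (", diploid_number, ")")
  if (!is.data.frame(ch_bands)) {
    if (is.null(ch_bands) || length(ch_bands) == 0 || is.na(ch_bands[1]))
      ch_bands <- NA_character_
    ch_bands <- parse_ch_bands(ch_bands[1])
  }
  bad <- ch_bands$chromosome_pair > diploid_number %/% 2L
  if (any(bad))
    stop("CH band on pair ", ch_bands$chromosome_pair[which(bad)[1]],
         " exceeds the ", diploid_number %/% 2L, " pairs of a 2n=",
         diploid_number, " karyotype")
  structure(list(species = species, sex = sex,
                 diploid_number = diploid_number,
                 biarmed_count = biarmed, uniarmed_count = uniarmed,
                 fundamental_number = diploid_number + biarmed,
                 ch_bands = ch_bands,
                 sex_system = sex_system),
            class = "karyotype_record")
}

#' @export
print.karyotype_record <- function(x, ...) {
  cat(sprintf("%s (%s): 2n = %d, KF = %s, FN = %d\n", x$species, x$sex,
              x$diploid_number,
              format_karyotype_formula(x$biarmed_count, x$uniarmed_count),
              x$fundamental_number))
  if (nrow(x$ch_bands))
    cat("  CH bands:", format_ch_bands(x$ch_bands), "\n")
  if (!is.na(x$sex_system)) cat("  sex system:", x$sex_system, "\n")
  invisible(x)
}

#' Fundamental number of a karyotype
#'
#' FN counts chromosome arms: bi-armed (meta-/submetacentric) chromosomes
#' contribute two arms, uni-armed (subtelo-/acrocentric) one, so
#' FN = 2n + bi-armed count.
#'
#' @param record A [karyotype_record()].
#' @return Positive integer FN.
#' @export
fundamental_number <- function(record) {
  stopifnot(inherits(record, "karyotype_record"))
  record$diploid_number + record$biarmed_count
}

#' Pairwise karyotype divergence index
#'
#' The divergence index between two karyotypes is
#' `|delta 2n| / 2 + |delta FN| / 2`, in units of chromosome-pair changes.
#' It is a semimetric: non-negative, symmetric, and zero exactly when both
#' 2n and FN coincide.
#'
#' @param a,b [karyotype_record()] objects.
#' @return Non-negative real divergence in index units.
#' @examples
#' x <- karyotype_record("sp1", 40, "8m-sm/32st-a")
#' y <- karyotype_record("sp2", 36, "6m-sm/30st-a")
#' divergence_index(x, y)  # |40-36|/2 + |48-42|/2 = 5
#' @export
divergence_index <- function(a, b) {
  stopifnot(inherits(a, "karyotype_record"), inherits(b, "karyotype_record"))
  abs(a$diploid_number - b$diploid_number) / 2 +
    abs(a$fundamental_number - b$fundamental_number) / 2
}

#' All-pairs karyotype divergence matrix
#'
#' @param records List of [karyotype_record()] objects with unique species
#'   names (use [select_sex()] first for tables holding both sexes).
#' @return Symmetric numeric matrix with zero diagonal, species names as
#'   dimnames.
#' @export
divergence_matrix <- function(records) {
  stopifnot(is.list(records), length(records) >= 2L)
  nm <- vapply(records, function(r) r$species, character(1))
  if (anyDuplicated(nm))
    stop("duplicate species names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  n <- length(records)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- divergence_index(records[[i]], records[[j]])
  }
  m
}

#' Compare CH band sets of two karyotypes
#'
#' Band identity is the triple (chromosome pair, arm, position); the three
#' counts partition the union of the two band sets.
#'
#' @param a,b [karyotype_record()] objects.
#' @return Named integer vector `shared`, `a_only`, `b_only`.
#' @export
compare_ch_bands <- function(a, b) {
  key <- function(r) unique(with(r$ch_bands,
                                 paste(chromosome_pair, arm, position)))
  ka <- key(a); kb <- key(b)
  c(shared = length(intersect(ka, kb)),
    a_only = length(setdiff(ka, kb)),
    b_only = length(setdiff(kb, ka)))
}

#' Read a karyotype table from TSV
#'
#' Expected header columns: `species`, `sex`, `diploid_number`,
#' `karyotype_formula`, `ch_bands`, `sex_system` (last two optional).
#' Species with a sex-chromosome system may appear on one row per sex.
#'
#' @param path Path to a tab-separated file.
#' @return A list of [karyotype_record()] objects (class
#'   `karyotype_table`).
#' @seealso [select_sex()], [karyevol_example()]
#' @export
read_karyotype_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "sex", "diploid_number", "karyotype_formula")
  if (!all(need %in% names(d)))
    stop("karyotype table must have columns: ", paste(need, collapse = ", "))
  if (!"ch_bands" %in% names(d)) d$ch_bands <- ""
  if (!"sex_system" %in% names(d)) d$sex_system <- NA_character_
  recs <- lapply(seq_len(nrow(d)), function(i)
    karyotype_record(d$species[i], d$diploid_number[i],
                     d$karyotype_formula[i],
                     sex = d$sex[i],
                     ch_bands = d$ch_bands[i],
                     sex_system = if (is.na(d$sex_system[i]) ||
                                      !nzchar(d$sex_system[i]))
                       NA_character_ else d$sex_system[i]))
  structure(recs, class = "karyotype_table")
}

#' Write a karyotype table to TSV
#' @param records List of karyotype records.
#' @param path Output path.
#' @export
write_karyotype_table <- function(records, path) {
  d <- do.call(rbind, lapply(records, function(r)
    data.frame(species = r$species, sex = r$sex,
               diploid_number = r$diploid_number,
               karyotype_formula =
                 format_karyotype_formula(r$biarmed_count, r$uniarmed_count),
               ch_bands = format_ch_bands(r$ch_bands),
               sex_system = r$sex_system, stringsAsFactors = FALSE)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pick one record per species by sex preference
#'
#' For species carrying a sex-chromosome system the table holds one row per
#' sex; interspecific comparison defaults to the female complement (even
#' and homomorphic). Falls back to whatever single record a species has.
#'
#' @param records A `karyotype_table` or list of records.
#' @param prefer `"female"` (default) or `"male"`.
#' @return List of records, one per species, in first-appearance order.
#' @export
select_sex <- function(records, prefer = c("female", "male")) {
  prefer <- match.arg(prefer)
  sp <- vapply(records, function(r) r$species, character(1))
  out <- lapply(unique(sp), function(s) {
    rs <- records[sp == s]
    sexes <- vapply(rs, function(r) r$sex, character(1))
    if (prefer %in% sexes) rs[[match(prefer, sexes)]]
    else if ("unspecified" %in% sexes) rs[[match("unspecified", sexes)]]
    else rs[[1]]
  })
  structure(out, class = "karyotype_table")
}

#' Diploid numbers as a named vector
#'
#' @param records Karyotype table.
#' @param prefer Sex preference passed to [select_sex()].
#' @return Named numeric vector of 2n values, one per species.
#' @export
diploid_numbers <- function(records, prefer = "female") {
  recs <- select_sex(records, prefer)
  stats::setNames(vapply(recs, function(r) as.numeric(r$diploid_number),
                         numeric(1)),
                  vapply(recs, function(r) r$species, character(1)))
}

#' Write a divergence matrix as square TSV or PHYLIP
#'
#' @param m Symmetric matrix from [divergence_matrix()].
#' @param path Output path.
#' @param format `"tsv"` (taxa as first row and column) or `"phylip"`
#'   (square PHYLIP distance matrix).
#' @export
write_divergence_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(data.frame(species = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(formatC(rownames(m)[i], width = -10),
                       paste(sprintf("%.6f", m[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a square TSV divergence matrix
#' @param path Path written by [write_divergence_matrix()] (tsv format).
#' @return Symmetric numeric matrix.
#' @export
read_divergence_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Path to a packaged example data file
#'
#' @param file One of `"karyotypes"` (transcription of the published
#'   Brachyhypopomus cytogenetic compilation), `"tree"` (synthetic
#'   reconstruction of the published tree topology), `"outgroups"`
#'   (documented outgroup diploid-number assumptions, synthetic), or a
#'   literal file name under `extdata/`; `NULL` lists available files.
#' @return File path.
#' @export
karyevol_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "karyevol")
  if (is.null(file)) return(list.files(dir))
  alias <- c(karyotypes = "brachyhypopomus_karyotypes.tsv",
             tree = "hypopomidae_tree_synthetic.nwk",
             outgroups = "outgroup_diploids_synthetic.tsv")
  if (file %in% names(alias)) file <- alias[[file]]
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged file ", sQuote(file))
  path
}
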