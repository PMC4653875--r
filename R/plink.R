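# PLINK text PED/MAP input/output plus a sidecar TSV carrying panel tags.
# Only the text formats are supported (no binary BED).

#' Write a genotype panel as PLINK text PED/MAP
#'
#' MAP columns are chromosome, SNP id, genetic distance (written as 0) and
#' bp position. In the PED file the counted (second) allele is written as
#' `2` and the other allele as `1`; missing genotypes are `0 0`. Family id is
#' the sire id (or the animal id for founders), paternal id is the sire id.
#' Panel tags go to `<prefix>.panels.tsv` (columns `snp_id`, `panel`).
#'
#' @param panel A `genotype_panel`.
#' @param prefix Path prefix; writes `<prefix>.ped`, `<prefix>.map`,
#'   `<prefix>.panels.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_plink <- function(panel, prefix) {
  map <- data.frame(chrom = panel$map$chrom, snp_id = panel$map$snp_id,
                    cm = 0, pos = panel$map$pos)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  code <- c(`0` = "1 1", `1` = "1 2", `2` = "2 2")
  dos <- panel$dosages
  geno <- matrix("0 0", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  geno[ok] <- code[as.character(dos[ok])]
  sire <- ifelse(is.na(panel$sire_of), "0", panel$sire_of)
  fam <- ifelse(sire == "0", rownames(dos), sire)
  lines <- paste(fam, rownames(dos), sire, 0, 0, -9,
                 apply(geno, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  tags <- rbind(
    data.frame(snp_id = panel$panels$sparse7, panel = "sparse7"),
    data.frame(snp_id = panel$panels$sparse50, panel = "sparse50")
  )
  utils::write.table(tags, paste0(prefix, ".panels.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  invisible(paste0(prefix, c(".ped", ".map", ".panels.tsv")))
}

#' Read PLINK text PED/MAP into a genotype panel
#'
#' Dosages count the second allele of each SNP. For numeric allele codes the
#' second allele is `2`; otherwise it is the lexicographically later of the
#' two alleles observed at the SNP. `0 0` is read as missing. If a
#' `<prefix>.panels.tsv` sidecar exists its tags are restored.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return A `genotype_panel` (target frequencies unknown, set to `NA`).
#' @export
read_plink <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path)) {
    stop("missing ", map_path, " or ", ped_path, call. = FALSE)
  }
  map_raw <- utils::read.table(map_path, stringsAsFactors = FALSE)
  if (ncol(map_raw) < 4) stop("malformed MAP: expected 4 columns", call. = FALSE)
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  n <- length(lines)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  ids <- character(n); sire <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m) {
      stop(sprintf("malformed PED line %d: %d fields, expected %d",
                   i, length(f), 6 + 2 * m), call. = FALSE)
    }
    ids[i] <- f[2]
    sire[i] <- f[3]
    g <- f[-(1:6)]
    a1[i, ] <- g[seq(1, 2 * m, by = 2)]
    a2[i, ] <- g[seq(2, 2 * m, by = 2)]
  }
  dos <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2) {
      stop("SNP ", map_raw[j, 2], " has more than two alleles", call. = FALSE)
    }
    counted <- if (length(alleles) == 0) {
      NA_character_
    } else if (all(alleles %in% c("1", "2"))) {
      "2"
    } else {
      alleles[length(alleles)]
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    if (!is.na(counted)) {
      dos[, j] <- (a1[, j] == counted) + (a2[, j] == counted)
    } else {
      dos[, j] <- 0L
    }
    dos[miss, j] <- NA_integer_
  }
  rownames(dos) <- ids
  colnames(dos) <- map_raw[, 2]
  map <- data.frame(snp_id = as.character(map_raw[, 2]), chrom = map_raw[, 1],
                    pos = map_raw[, 4], target_freq = NA_real_,
                    stringsAsFactors = FALSE)
  panels <- NULL
  tag_path <- paste0(prefix, ".panels.tsv")
  if (file.exists(tag_path)) {
    tags <- utils::read.table(tag_path, header = TRUE, stringsAsFactors = FALSE)
    panels <- list(sparse7 = tags$snp_id[tags$panel == "sparse7"],
                   sparse50 = sort(unique(tags$snp_id)))
  }
  sire_of <- stats::setNames(ifelse(sire == "0", NA_character_, sire), ids)
  genotype_panel(dos, map, panels = panels, sire_of = sire_of)
}
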