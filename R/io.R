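NA_TOKEN <- "."

na_out <- function(x) ifelse(is.na(x), NA_TOKEN, as.character(x))
na_in <- function(x) {
  x <- as.character(x)
  x[!nzchar(x) | x == NA_TOKEN] <- NA_character_
  x
}

# Keep one annotation per variant key: the most severe consequence wins,
# earlier rows break ties.
collapse_annotations <- function(v) {
  if (!anyDuplicated(v$key)) return(v)
  sev <- match(v$consequence, consequence_classes())
  ord <- order(match(v$key, unique(v$key)), sev)
  v <- v[ord, , drop = FALSE]
  v[!duplicated(v$key), , drop = FALSE]
}

#' Read a variant+genotype table
#'
#' Two dialects are supported. `annotated_tsv` is this package's exchange
#' format: columns `chrom, pos, ref, alt, gene, cdna, protein, consequence`
#' followed by one zygosity column per sample. `vcf` is VCF 4.x read through
#' `vcfR`, with annotations taken from the INFO keys `GENE`, `CDNA`, `PROT`
#' and `CSQ` (the consequence term); multi-allelic rows are split into one
#' variant per alternate allele before anything else happens.
#'
#' @param path File path.
#' @param dialect `"annotated_tsv"` or `"vcf"`.
#' @return A [variant_cohort()].
#' @export
read_variant_table <- function(path, dialect = c("annotated_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "annotated_tsv") read_annotated_tsv(path) else read_vcf_cohort(path)
}

read_annotated_tsv <- function(path) {
  fixed <- c("chrom", "pos", "ref", "alt", "gene", "cdna", "protein",
             "consequence")
  d <- utils::read.delim(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(fixed, names(d))
  if (length(missing_cols))
    stop("annotated_tsv is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  sample_cols <- setdiff(names(d), fixed)
  if (nrow(d) == 0) {
    return(variant_cohort(variant_table(character(), integer(), character(),
                                        character())[0, ],
                          genotype_table(character(), character(), character()),
                          samples = sample_cols))
  }
  pos <- suppressWarnings(as.integer(d$pos))
  bad <- which(is.na(pos))
  if (length(bad))
    stop("malformed row at line ", bad[[1]] + 1L,
         ": position '", d$pos[bad[[1]]], "' is not an integer")
  v <- variant_table(d$chrom, pos, d$ref, d$alt, na_in(d$gene), na_in(d$cdna),
                     na_in(d$protein), d$consequence)
  gt <- do.call(rbind, lapply(sample_cols, function(s) {
    z <- d[[s]]
    keep <- nzchar(z) & z != NA_TOKEN
    if (!any(keep)) return(NULL)
    data.frame(sample_id = s, key = v$key[keep], zygosity = z[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(gt))
    gt <- data.frame(sample_id = character(), key = character(),
                     zygosity = character())
  variant_cohort(v, gt, samples = sample_cols)
}

read_vcf_cohort <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (nrow(fix) == 0) {
    return(variant_cohort(variant_table(character(), integer(), character(),
                                        character())[0, ],
                          genotype_table(character(), character(), character()),
                          samples = samples))
  }
  info_field <- function(info, field) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", field, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2) x[[2]] else NA_character_, "")
  }
  gt_raw <- if (length(samples)) vcfR::extract.gt(vcf, element = "GT") else NULL
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[[i]], ",", fixed = TRUE)[[1]]
    info <- fix$INFO[[i]]
    lapply(seq_along(alts), function(k) {
      key <- variant_key(fix$CHROM[[i]], fix$POS[[i]], fix$REF[[i]], alts[[k]])
      zyg <- character(0)
      if (length(samples)) {
        g <- gt_raw[i, samples]
        alleles <- strsplit(gsub("\\|", "/", ifelse(is.na(g), "./.", g)), "/")
        zyg <- vapply(alleles, function(a) {
          if (any(a == ".")) return("missing")
          hits <- sum(a == as.character(k))
          c("hom_ref", "het", "hom_alt")[hits + 1L]
        }, "")
      }
      list(chrom = fix$CHROM[[i]], pos = as.integer(fix$POS[[i]]),
           ref = fix$REF[[i]], alt = alts[[k]],
           gene = info_field(info, "GENE"), cdna = info_field(info, "CDNA"),
           protein = info_field(info, "PROT"),
           consequence = info_field(info, "CSQ"),
           zygosity = zyg, key = key)
    })
  })
  rows <- unlist(rows, recursive = FALSE)
  csq <- vapply(rows, `[[`, "", "consequence")
  csq[is.na(csq)] <- "other"
  v <- variant_table(vapply(rows, `[[`, "", "chrom"),
                     vapply(rows, `[[`, 1L, "pos"),
                     vapply(rows, `[[`, "", "ref"),
                     vapply(rows, `[[`, "", "alt"),
                     vapply(rows, `[[`, "", "gene"),
                     vapply(rows, `[[`, "", "cdna"),
                     vapply(rows, `[[`, "", "protein"),
                     csq)
  gt <- do.call(rbind, lapply(seq_along(rows), function(j) {
    z <- rows[[j]]$zygosity
    keep <- z != "hom_ref"
    if (!any(keep)) return(NULL)
    data.frame(sample_id = samples[keep], key = v$key[[j]], zygosity = z[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(gt))
    gt <- data.frame(sample_id = character(), key = character(),
                     zygosity = character())
  variant_cohort(collapse_annotations(v), gt, samples = samples)
}

#' Write a variant cohort
#'
#' Inverse of [read_variant_table()]. The `annotated_tsv` dialect round-trips
#' every field bit-exactly; `vcf` writes a minimal VCF 4.2 body with the
#' annotation INFO keys this package reads back.
#'
#' @param cohort A [variant_cohort()].
#' @param path Output path.
#' @param dialect `"annotated_tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(cohort, path,
                                dialect = c("annotated_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  v <- cohort$variants
  g <- cohort$genotypes
  samples <- cohort$samples
  if (dialect == "annotated_tsv") {
    out <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                      gene = na_out(v$gene), cdna = na_out(v$cdna),
                      protein = na_out(v$protein), consequence = v$consequence,
                      check.names = FALSE, stringsAsFactors = FALSE)
    for (s in samples) {
      z <- rep("hom_ref", nrow(v))
      gs <- g[g$sample_id == s, , drop = FALSE]
      z[match(gs$key, v$key)] <- gs$zygosity
      out[[s]] <- z
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
             "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"HGVS cDNA change\">",
             "##INFO=<ID=PROT,Number=1,Type=String,Description=\"Protein change, single-letter\">",
             "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    ord <- order(v$chrom, v$pos)
    body <- vapply(ord, function(i) {
      info <- paste0(c(paste0("GENE=", v$gene[i])[!is.na(v$gene[i])],
                       paste0("CDNA=", v$cdna[i])[!is.na(v$cdna[i])],
                       paste0("PROT=", v$protein[i])[!is.na(v$protein[i])],
                       paste0("CSQ=", v$consequence[i])),
                     collapse = ";")
      gts <- vapply(samples, function(s) {
        switch(zygosity_of(g, s, v$key[i]),
               hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
      }, "")
      paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
              info, "GT", gts), collapse = "\t")
    }, "")
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a pedigree (PED) file
#'
#' Standard 6-column PED: family, individual, father, mother, sex, phenotype.
#' Every affected individual (phenotype 2) becomes a trio proband; a parent
#' id of `"0"` marks that parent unavailable.
#'
#' @param path PED file path.
#' @return A `data.frame` of trios: `proband_id`, `father_id`, `mother_id`,
#'   `father_available`, `mother_available`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.table(path, colClasses = "character",
                         col.names = c("fam", "id", "father", "mother",
                                       "sex", "phenotype"))
  pro <- d[d$phenotype == "2", , drop = FALSE]
  if (anyDuplicated(pro$id))
    stop("duplicate proband id(s): ",
         paste(unique(pro$id[duplicated(pro$id)]), collapse = ", "))
  trio_table(pro$id,
             ifelse(pro$father == "0", NA, pro$father),
             ifelse(pro$mother == "0", NA, pro$mother))
}

#' Construct a trio table
#'
#' @param proband_id Proband labels.
#' @param father_id,mother_id Parent labels; `NA` (or `"0"`) marks a parent
#'   without available DNA.
#' @return A `data.frame` with availability flags.
#' @export
trio_table <- function(proband_id, father_id, mother_id) {
  father_id[!is.na(father_id) & father_id == "0"] <- NA
  mother_id[!is.na(mother_id) & mother_id == "0"] <- NA
  t <- data.frame(proband_id = as.character(proband_id),
                  father_id = as.character(father_id),
                  mother_id = as.character(mother_id),
                  father_available = !is.na(father_id),
                  mother_available = !is.na(mother_id),
                  stringsAsFactors = FALSE)
  same <- !is.na(t$father_id) & (t$father_id == t$proband_id) |
    !is.na(t$mother_id) & (t$mother_id == t$proband_id) |
    (!is.na(t$father_id) & !is.na(t$mother_id) & t$father_id == t$mother_id)
  if (any(same)) stop("proband, father and mother ids must be distinct")
  t
}

#' Read a gene set (one symbol per line)
#'
#' Symbols are upper-cased and deduplicated; blank lines are ignored.
#'
#' @param path File path.
#' @param name Label for the set.
#' @return An object of class `gene_set`: a character vector of symbols with
#'   a `name` attribute.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  sym <- trimws(readLines(path, warn = FALSE))
  sym <- unique(toupper(sym[nzchar(sym)]))
  if (length(sym) == 0) stop("gene set file is empty: ", path)
  gene_set(sym, name)
}

#' @rdname read_gene_set
#' @param symbols Character vector of gene symbols.
#' @export
gene_set <- function(symbols, name = "gene_set") {
  symbols <- unique(toupper(trimws(as.character(symbols))))
  symbols <- symbols[nzchar(symbols)]
  if (length(symbols) == 0) stop("gene set must contain at least one symbol")
  structure(symbols, name = name, class = c("gene_set", "character"))
}

#' Known-variant database
#'
#' A dbSNP-like table of registered variants: `chrom, pos, ref, alt,
#' source_id` (TSV with header).
#'
#' @param path TSV path.
#' @return A `data.frame` with a `key` column.
#' @export
read_known_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, colClasses = "character")
  known_db(d$chrom, as.integer(d$pos), d$ref, d$alt, d$source_id)
}

#' @rdname read_known_db
#' @param chrom,pos,ref,alt Identity components of the registered variants.
#' @param source_id Database record labels (e.g. rs numbers).
#' @export
known_db <- function(chrom, pos, ref, alt, source_id = NA_character_) {
  pos <- as.integer(pos)
  if (length(pos) && (any(is.na(pos)) || any(pos < 1)))
    stop("known-variant positions must be integers >= 1")
  data.frame(chrom = as.character(chrom), pos = pos,
             ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
             source_id = rep_len(as.character(source_id), length(pos)),
             key = variant_key(chrom, pos, toupper(ref), toupper(alt)),
             stringsAsFactors = FALSE)
}

#' @rdname read_known_db
#' @param db A known-variant table.
#' @export
write_known_db <- function(db, path) {
  utils::write.table(db[c("chrom", "pos", "ref", "alt", "source_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format genotype table (controls, extension samples)
#'
#' TSV with header `sample_id, chrom, pos, ref, alt, zygosity`. Samples
#' without a record at a variant are implicitly homozygous reference.
#'
#' @param path TSV path.
#' @return A genotype table ([genotype_table()]) with a `samples` attribute
#'   listing all sample ids seen.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, colClasses = "character")
  g <- genotype_table(d$sample_id,
                      variant_key(d$chrom, as.integer(d$pos), toupper(d$ref),
                                  toupper(d$alt)),
                      d$zygosity)
  attr(g, "samples") <- unique(d$sample_id)
  g
}

#' @rdname read_genotype_table
#' @param genotypes A genotype table whose keys are `chrom:pos:ref:alt`.
#' @export
write_genotype_table <- function(genotypes, path) {
  parts <- strsplit(genotypes$key, ":", fixed = TRUE)
  out <- data.frame(sample_id = genotypes$sample_id,
                    chrom = vapply(parts, `[[`, "", 1),
                    pos = vapply(parts, `[[`, "", 2),
                    ref = vapply(parts, `[[`, "", 3),
                    alt = vapply(parts, `[[`, "", 4),
                    zygosity = genotypes$zygosity, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Confirmation oracle
#'
#' The artifact-level stand-in for Sanger validation: a lookup declaring each
#' (variant, sample) observation confirmed or a sequencing error. TSV columns:
#' `chrom, pos, ref, alt, sample_id, confirmed` (true/false).
#'
#' @param path TSV path.
#' @return A `data.frame` with columns `key`, `sample_id`, `confirmed`.
#' @export
read_confirmation_oracle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, colClasses = "character")
  confirmation_oracle(variant_key(d$chrom, as.integer(d$pos), toupper(d$ref),
                                  toupper(d$alt)),
                      d$sample_id,
                      tolower(d$confirmed) %in% c("true", "t", "1", "yes"))
}

#' @rdname read_confirmation_oracle
#' @param key Variant keys.
#' @param sample_id Sample labels.
#' @param confirmed Logical vector.
#' @export
confirmation_oracle <- function(key, sample_id, confirmed) {
  data.frame(key = as.character(key), sample_id = as.character(sample_id),
             confirmed = as.logical(confirmed), stringsAsFactors = FALSE)
}

#' @rdname read_confirmation_oracle
#' @param oracle An oracle table.
#' @export
write_confirmation_oracle <- function(oracle, path) {
  parts <- strsplit(oracle$key, ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                    pos = vapply(parts, `[[`, "", 2),
                    ref = vapply(parts, `[[`, "", 3),
                    alt = vapply(parts, `[[`, "", 4),
                    sample_id = oracle$sample_id,
                    confirmed = tolower(oracle$confirmed),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_pedigree
#' @param trios A trio table.
#' @param path Output path.
#' @export
write_pedigree <- function(trios, path) {
  lines <- vapply(seq_len(nrow(trios)), function(i) {
    t <- trios[i, ]
    paste(c(paste0("FAM", i), t$proband_id,
            if (t$father_available) t$father_id else "0",
            if (t$mother_available) t$mother_id else "0",
            "0", "2"), collapse = "\t")
  }, "")
  parent_lines <- unlist(lapply(seq_len(nrow(trios)), function(i) {
    t <- trios[i, ]
    c(if (t$father_available)
        paste(paste0("FAM", i), t$father_id, "0", "0", "1", "1", sep = "\t"),
      if (t$mother_available)
        paste(paste0("FAM", i), t$mother_id, "0", "0", "2", "1", sep = "\t"))
  }))
  writeLines(c(lines, parent_lines), path)
  invisible(path)
}
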