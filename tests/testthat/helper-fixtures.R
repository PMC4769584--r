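# small fixtures built in code

toy_geno <- function(dos, chrom = NULL, pos = NULL) {
  m <- ncol(dos)
  genotype_matrix(dos,
                  data.frame(chrom = chrom %||% rep(1L, m),
                             pos = pos %||% seq_len(m),
                             id = sprintf("snp%02d", seq_len(m))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_geno <- function(n, m, seed = 1, freq = NULL) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(m, 0.1, 0.9)
  dos <- sapply(freq, function(p) rbinom(n, 2, p))
  toy_geno(dos)
}

# minimal single-sample-block VCF text
write_toy_vcf <- function(path, gt_rows, ids, chrom = 1, pos = NULL) {
  n_var <- length(gt_rows)
  pos <- pos %||% seq_len(n_var) * 100
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(n_var), function(i) {
    paste(c(chrom, pos[i], paste0("rs", i), "A", "G", ".", "PASS", ".",
            "GT", gt_rows[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# compose a PLINK .bed byte stream by hand (independent of write_plink):
# 2-bit codes, individual-minor within byte; 00=hom A1, 01=missing,
# 10=het, 11=hom A2
compose_bed_bytes <- function(dos_matrix) {
  code_of <- function(d) {
    if (is.na(d)) return(1L)  # 01 missing
    c(`0` = 3L, `1` = 2L, `2` = 0L)[[as.character(d)]]
  }
  n <- nrow(dos_matrix)
  bytes <- integer(0)
  for (j in seq_len(ncol(dos_matrix))) {
    codes <- vapply(dos_matrix[, j], code_of, integer(1))
    codes <- c(codes, rep(0L, (-n) %% 4))  # zero padding bits
    for (k in seq(1, length(codes), by = 4)) {
      q <- codes[k:(k + 3)]
      bytes <- c(bytes, sum(q * c(1L, 4L, 16L, 64L)))
    }
  }
  as.raw(c(0x6c, 0x1b, 0x01, bytes))
}
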