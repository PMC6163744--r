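#!/usr/bin/env Rscript
# Stratify posts into engagement tertiles and extract each group's
# distinctive vocabulary by tf-idf over the three concatenated groups
# (terms common to all engagement levels get weight zero and drop out).

suppressPackageStartupMessages(library(postmine))

posts <- read_posts("results/data/posts.tsv")
tok <- token_config(stopwords = spanish_stopwords())

tert <- tertile_split(posts)
readr::write_csv(tert$assignment, "results/engagement_groups.csv")
cat(sprintf("tertile thresholds: low <= %g < medium <= %g < high\n",
            tert$q_low, tert$q_high))
print(table(tert$assignment$group))

groups <- split(posts$message, tert$assignment$group)
corpora <- lapply(groups, build_corpus, config = tok)
weights <- tfidf_by_group(corpora$low, corpora$medium, corpora$high)
top <- dplyr::bind_rows(
  lapply(split(weights, weights$group), top_terms, k = 15), .id = "group")
readr::write_csv(top, "results/tfidf_terms.csv")

for (g in c("high", "medium", "low")) {
  cat(sprintf("\ntop terms, %s engagement: %s\n", g,
              paste(head(top$term[top$group == g], 6), collapse = ", ")))
}
cat("\nwritten: results/engagement_groups.csv, results/tfidf_terms.csv\n")
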