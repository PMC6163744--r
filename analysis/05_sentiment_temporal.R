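#!/usr/bin/env Rscript
# Sentiment scoring, its correlation screen against the interaction counts,
# and the temporal analysis: posting frequency and mean polarity by hour,
# weekday and daypart, with one-way ANOVA screens.

suppressPackageStartupMessages(library(postmine))

posts <- read_posts("results/data/posts.tsv")
sent <- score_posts(posts)
eng <- engagement(posts)

grid <- correlation_matrix(sent, posts)
readr::write_csv(grid, "results/correlations.csv")
if (any(grid$highlighted)) {
  cat("highlighted correlations (|rho| >= 0.10):\n")
  print(as.data.frame(grid[grid$highlighted, ]), row.names = FALSE, digits = 2)
} else {
  cat("no correlation reaches |rho| >= 0.10 (sentiment and interaction\n")
  cat("counts are generated independently in the synthetic corpus)\n")
}

hour_freq <- aggregate_metric(posts, eng, by = "hour", metric_name = "engagement")
hour_pol <- aggregate_metric(posts, sent$polarity, by = "hour",
                             metric_name = "polarity")
day_freq <- aggregate_metric(posts, eng, by = "weekday",
                             metric_name = "engagement")
part_pol <- aggregate_metric(posts, sent$polarity, by = "daypart",
                             metric_name = "polarity")
readr::write_csv(hour_freq, "results/temporal_hour_engagement.csv")
readr::write_csv(hour_pol, "results/temporal_hour_polarity.csv")
readr::write_csv(day_freq, "results/temporal_weekday.csv")
readr::write_csv(part_pol, "results/temporal_daypart_polarity.csv")

busiest <- hour_freq$key[order(-hour_freq$n)][1:3]
cat(sprintf("\nbusiest posting hours: %s\n",
            paste(as.character(busiest), collapse = ", ")))
cat("mean polarity by daypart:\n")
print(as.data.frame(part_pol), row.names = FALSE, digits = 2)

anovas <- list(
  polarity_hour = one_way_anova(sent$polarity, post_hour(posts)),
  polarity_weekday = one_way_anova(sent$polarity, post_weekday(posts)),
  engagement_hour = one_way_anova(eng, post_hour(posts)),
  engagement_weekday = one_way_anova(eng, post_weekday(posts))
)
an <- tibble::tibble(
  comparison = names(anovas),
  F = sapply(anovas, `[[`, "statistic"),
  p_value = sapply(anovas, `[[`, "p_value")
)
readr::write_csv(an, "results/anova.csv")
cat("\nANOVA screens:\n")
print(as.data.frame(an), row.names = FALSE, digits = 3)
cat("\nwritten: results/correlations.csv, results/temporal_*.csv, results/anova.csv\n")
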