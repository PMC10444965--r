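toy_corpus.conll  four-sentence disease corpus carrying the worked substitution
                  examples (aniridia, alkaptonuria, myalgias, hypertension /
                  intracellular); CoNLL-BIO, token TAB tag.
toy_kg.tsv        miniature synthetic UMLS-style knowledge graph with the
                  documented neighbourhoods of those concepts; KG-TSV
                  (head, relation, tail, head semtypes, tail semtypes).
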