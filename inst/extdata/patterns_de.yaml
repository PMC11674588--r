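- category: affirmative_pneumothorax
  pattern: \b(pneumothorax|pneu|ptx)\b
  label: pneumothorax mention
- category: negated_pneumothorax
  pattern: \bkein (pneumothorax|pneu|ptx)\b
  label: 'negated: kein {m}'
- category: negated_pneumothorax
  pattern: \bkein nachweis eines (pneumothorax|pneu|ptx)\b
  label: 'negated: kein nachweis eines {m}'
- category: negated_pneumothorax
  pattern: \bkeine hinweise auf (pneumothorax|pneu|ptx)\b
  label: 'negated: keine hinweise auf {m}'
- category: negated_pneumothorax
  pattern: \bkein anhalt fuer (pneumothorax|pneu|ptx)\b
  label: 'negated: kein anhalt fuer {m}'
- category: negated_pneumothorax
  pattern: \b(pneumothorax|pneu|ptx) nicht nachweisbar\b
  label: 'negated: {m} nicht nachweisbar'
- category: negated_pneumothorax
  pattern: \bausschluss (pneumothorax|pneu|ptx)\b
  label: 'negated: ausschluss {m}'
- category: contraindication
  pattern: \bz n thorakotomie\b
  label: 'contraindication: z.n. thorakotomie'
- category: contraindication
  pattern: \bthoraxtrauma nach sturz\b
  label: 'contraindication: thoraxtrauma nach sturz'
- category: contraindication
  pattern: \bvorbekannter pneumothorax\b
  label: 'contraindication: vorbekannter pneumothorax'
- category: contraindication
  pattern: \bz n thoraxchirurgischem eingriff\b
  label: 'contraindication: z.n. thoraxchirurgischem eingriff'
- category: contraindication
  pattern: \brippenserienfraktur links\b
  label: 'contraindication: rippenserienfraktur links'
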