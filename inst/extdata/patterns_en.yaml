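- category: affirmative_pneumothorax
  pattern: \b(pneumothorax|ptx)\b
  label: pneumothorax mention
- category: negated_pneumothorax
  pattern: \bno (pneumothorax|ptx)\b
  label: 'negated: no {m}'
- category: negated_pneumothorax
  pattern: \bno evidence of (pneumothorax|ptx)\b
  label: 'negated: no evidence of {m}'
- category: negated_pneumothorax
  pattern: \bwithout evidence of (pneumothorax|ptx)\b
  label: 'negated: without evidence of {m}'
- category: negated_pneumothorax
  pattern: \b(pneumothorax|ptx) is not seen\b
  label: 'negated: {m} is not seen'
- category: negated_pneumothorax
  pattern: \brule out (pneumothorax|ptx)\b
  label: 'negated: rule out {m}'
- category: contraindication
  pattern: \bstatus post thoracotomy\b
  label: 'contraindication: status post thoracotomy'
- category: contraindication
  pattern: \bknown prior pneumothorax\b
  label: 'contraindication: known prior pneumothorax'
- category: contraindication
  pattern: \brib fractures after chest trauma\b
  label: 'contraindication: rib fractures after chest trauma'
- category: contraindication
  pattern: \brecent thoracic surgery\b
  label: 'contraindication: recent thoracic surgery'
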