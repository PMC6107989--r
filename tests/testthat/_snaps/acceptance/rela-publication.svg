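<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="760.00" height="181.00" viewBox="0 0 760.00 181.00">
  <rect x="0" y="0" width="760.00" height="181.00" fill="#FFFFFF"/>
  <rect x="8.00" y="12.00" width="592.00" height="140.00" fill="#FFFFFF"/>
  <rect x="99.90" y="68.00" width="454.56" height="28.00" fill="#BEBEBE" stroke="#000000" stroke-width="1"/>
  <text x="89.97" y="85.32" font-family="Helvetica, Arial, sans-serif" font-size="9.48" text-anchor="end" fill="#000000">TF65_HUMAN</text>
  <rect x="114.78" y="64.50" width="237.20" height="35.00" fill="#E41A1C"/>
  <text x="99.08" y="169.00" font-family="Helvetica, Arial, sans-serif" font-size="9.00" text-anchor="middle" fill="#4D4D4D">0</text>
  <text x="181.72" y="169.00" font-family="Helvetica, Arial, sans-serif" font-size="9.00" text-anchor="middle" fill="#4D4D4D">100</text>
  <text x="264.37" y="169.00" font-family="Helvetica, Arial, sans-serif" font-size="9.00" text-anchor="middle" fill="#4D4D4D">200</text>
  <text x="347.02" y="169.00" font-family="Helvetica, Arial, sans-serif" font-size="9.00" text-anchor="middle" fill="#4D4D4D">300</text>
  <text x="429.66" y="169.00" font-family="Helvetica, Arial, sans-serif" font-size="9.00" text-anchor="middle" fill="#4D4D4D">400</text>
  <text x="512.31" y="169.00" font-family="Helvetica, Arial, sans-serif" font-size="9.00" text-anchor="middle" fill="#4D4D4D">500</text>
  <text x="594.96" y="169.00" font-family="Helvetica, Arial, sans-serif" font-size="9.00" text-anchor="middle" fill="#4D4D4D">600</text>
  <rect x="612.00" y="20.00" width="12" height="12" fill="#E41A1C"/>
  <text x="629.00" y="30.00" font-family="Helvetica, Arial, sans-serif" font-size="9.00" text-anchor="start" fill="#000000">RHD</text>
</svg>
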