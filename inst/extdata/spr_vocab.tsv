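ORGAN	lung
ORGAN	lung
ORGAN	lung
ORGAN	pleura
ORGAN	bronchus
ORGAN	trachea
LOCATION	right upper lobe
LOCATION	right middle lobe
LOCATION	right lower lobe
LOCATION	left upper lobe
LOCATION	left lower lobe
LOCATION	lingula
LOCATION	carina
LOCATION	main bronchus
OPNAME	lobectomy
OPNAME	wedge resection
OPNAME	pneumonectomy
OPNAME	segmentectomy
OPNAME	needle biopsy
OPNAME	bronchial washing
OPNAME	sleeve resection
HISTOLOGIC DIAGNOSIS	adenocarcinoma
HISTOLOGIC DIAGNOSIS	squamous cell carcinoma
HISTOLOGIC DIAGNOSIS	small cell carcinoma
HISTOLOGIC DIAGNOSIS	carcinoid tumor
HISTOLOGIC DIAGNOSIS	invasive mucinous adenocarcinoma
HISTOLOGIC DIAGNOSIS	large cell carcinoma
HISTOLOGIC DIAGNOSIS	granuloma
HISTOLOGIC DIAGNOSIS	organizing pneumonia
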