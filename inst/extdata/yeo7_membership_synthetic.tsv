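roi_name	network
ROI001	dorsal attention
ROI002	dorsal attention
ROI003	dorsal attention
ROI004	dorsal attention
ROI005	dorsal attention
ROI006	dorsal attention
ROI007	dorsal attention
ROI008	dorsal attention
ROI009	dorsal attention
ROI010	dorsal attention
ROI011	dorsal attention
ROI012	dorsal attention
ROI013	dorsal attention
ROI014	dorsal attention
ROI015	dorsal attention
ROI016	visual
ROI017	visual
ROI018	visual
ROI019	visual
ROI020	visual
ROI021	visual
ROI022	visual
ROI023	visual
ROI024	visual
ROI025	visual
ROI026	visual
ROI027	visual
ROI028	visual
ROI029	visual
ROI030	visual
ROI031	somato-motor
ROI032	somato-motor
ROI033	somato-motor
ROI034	somato-motor
ROI035	somato-motor
ROI036	somato-motor
ROI037	somato-motor
ROI038	somato-motor
ROI039	somato-motor
ROI040	somato-motor
ROI041	somato-motor
ROI042	somato-motor
ROI043	somato-motor
ROI044	somato-motor
ROI045	somato-motor
ROI046	ventral attention
ROI047	ventral attention
ROI048	ventral attention
ROI049	ventral attention
ROI050	ventral attention
ROI051	ventral attention
ROI052	ventral attention
ROI053	ventral attention
ROI054	ventral attention
ROI055	ventral attention
ROI056	ventral attention
ROI057	ventral attention
ROI058	ventral attention
ROI059	ventral attention
ROI060	ventral attention
ROI061	limbic
ROI062	limbic
ROI063	limbic
ROI064	limbic
ROI065	limbic
ROI066	limbic
ROI067	limbic
ROI068	limbic
ROI069	limbic
ROI070	limbic
ROI071	limbic
ROI072	limbic
ROI073	limbic
ROI074	limbic
ROI075	limbic
ROI076	fronto-parietal
ROI077	fronto-parietal
ROI078	fronto-parietal
ROI079	fronto-parietal
ROI080	fronto-parietal
ROI081	fronto-parietal
ROI082	fronto-parietal
ROI083	fronto-parietal
ROI084	fronto-parietal
ROI085	fronto-parietal
ROI086	fronto-parietal
ROI087	fronto-parietal
ROI088	fronto-parietal
ROI089	fronto-parietal
ROI090	fronto-parietal
ROI091	default-mode
ROI092	default-mode
ROI093	default-mode
ROI094	default-mode
ROI095	default-mode
ROI096	default-mode
ROI097	default-mode
ROI098	default-mode
ROI099	default-mode
ROI100	default-mode
ROI101	default-mode
ROI102	default-mode
ROI103	default-mode
ROI104	default-mode
ROI105	default-mode
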