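rx_id	components	indication_text	source
rx1	当归2钱;白芍3钱;柴胡2钱;茯苓3钱;薄荷1钱;丹皮2钱;山栀仁2钱;白术3钱;泽兰叶4钱;郁金2钱;甘草1钱	经闭气郁证, 肝郁气滞, 经闭不行, 面色青黄, 精神抑郁, 烦躁性急, 头昏耳鸣, 胸胁作胀, 食少嗳气, 舌尖红, 口燥, 脉弦数或弦紧。	classical
rx2	当归1钱;白芍1钱;茯苓1钱;白术1钱;贝母1钱;熟地1钱;山栀1钱;半夏6分;人参6分;柴胡6分;丹皮6分;陈皮6分;香附6分;川芎6分;甘草4分	暴怒伤肝, 抑郁忧思, 致肝火妄动, 发为鬓疽, 头眩, 痛彻太阳, 胸膈痞连两胁, 呕酸水。	classical
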